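test_that("simulation is reproducible to the last digit", {
  s1 <- simulateMovie(scenarioConfig(seed = 12))
  s2 <- simulateMovie(scenarioConfig(seed = 12))
  expect_identical(trackPoints(s1$tracks), trackPoints(s2$tracks))
  expect_identical(s1$labels, s2$labels)
  s3 <- simulateMovie(scenarioConfig(seed = 13))
  expect_false(identical(trackPoints(s1$tracks), trackPoints(s3$tracks)))
})

test_that("requested per-archetype counts are honored", {
  combos <- data.frame(marker = c("CD20", "PD1", "CD20"),
                       track_type = c("LM", "MT", "LD"),
                       action_type = c("PC", "IC", "AC"),
                       n = c(4L, 6L, 3L))
  sim <- simulateMovie(scenarioConfig(combos = combos, seed = 2,
                                      nFrames = 20))
  got <- table(sim$labels$track_type, sim$labels$action_type)
  expect_equal(got["LM", "PC"], 4)
  expect_equal(got["MT", "IC"], 6)
  expect_equal(got["LD", "AC"], 3)
  expect_equal(nTracks(sim$tracks), 13)
})

test_that("zero-track configurations give empty sets without error", {
  combos <- defaultCombos()
  combos$n <- 0L
  sim <- simulateMovie(scenarioConfig(combos = combos, seed = 1))
  expect_equal(nTracks(sim$tracks), 0)
  expect_equal(nrow(sim$labels), 0)
})

test_that("scenario validation rejects inconsistent archetypes", {
  bad <- data.frame(marker = "CD20", track_type = "LD",
                    action_type = "PC", n = 2L)
  expect_error(scenarioConfig(combos = bad), "PC")
  odd <- data.frame(marker = "CD20", track_type = "MT",
                    action_type = "IC", n = 3L)
  expect_error(scenarioConfig(combos = odd), "even")
  expect_error(archetypeParams(overlap = 1), "overlap")
  # overcrowded volume cannot honor the isolation distance
  crowd <- data.frame(marker = "CD20", track_type = "LM",
                      action_type = "PC", n = 60L)
  expect_error(
    simulateMovie(scenarioConfig(combos = crowd, boxUm = c(20, 20, 10),
                                 seed = 1)),
    "too small")
})

test_that("LM displacement is bounded by the confinement sphere", {
  par <- archetypeParams()
  for (s in 1:5) {
    lm <- simulateTrack("LM", nFrames = 60, seed = s)
    # jitter adds at most a few sd beyond the reflective boundary
    bound <- 2 * par$confinementRadiusUm[["LM"]] + 8 * par$jitterUm
    expect_lte(unname(displacementLength(lm)), bound)
  }
})

test_that("LD tracks are straighter and faster than MT tracks", {
  set.seed(44)
  strMT <- strLD <- spMT <- spLD <- numeric(60)
  for (i in 1:60) {
    mt <- simulateTrack("MT", nFrames = 40)
    ld <- simulateTrack("LD", nFrames = 40)
    strMT[i] <- straightness(mt); strLD[i] <- straightness(ld)
    spMT[i] <- speedMean(mt); spLD[i] <- speedMean(ld)
  }
  expect_gt(median(strLD), median(strMT))
  expect_gt(median(spLD), median(spMT))
  expect_gt(median(spLD), 5); expect_lt(median(spLD), 7)
})

test_that("zero persistence reduces LD to an unbiased random walk", {
  par <- archetypeParams()
  par$persistence <- 0
  par$jitterUm <- 0
  set.seed(55)
  pts <- do.call(rbind, lapply(1:80, function(i) {
    p <- trackPoints(simulateTrack("LD", nFrames = 60, params = par))
    p$track_id <- sprintf("rw%03d", i)
    p
  }))
  alpha <- fitAlpha(computeMSD(TrackSet(pts, 0.5), 10))
  expect_gt(alpha, 0.85); expect_lt(alpha, 1.15)
})

test_that("generated movies stay inside the imaging volume", {
  sim <- simulateMovie(scenarioConfig(seed = 6))
  p <- trackPoints(sim$tracks)
  box <- c(200, 200, 60)
  expect_true(all(p$x_um >= 0 & p$x_um <= box[1]))
  expect_true(all(p$y_um >= 0 & p$y_um <= box[2]))
  expect_true(all(p$z_um >= 0 & p$z_um <= box[3]))
  expect_true(validObject(sim$tracks))
  # default movie length survives the 5-minute duration filter untouched
  expect_equal(nTracks(filterMinDuration(sim$tracks, 5)),
               nTracks(sim$tracks))
})

test_that("IC pairs accumulate far more contact time than PC cells", {
  sim <- simulateMovie(scenarioConfig(seed = 21))
  st <- contactStats(contactEvents(buildTemporalGraph(sim$tracks, 7)),
                     sim$tracks)
  m <- merge(st, sim$labels, by = "track_id")
  durIC <- m$mean_contact_duration_frames[m$action_type == "IC"]
  durPC <- m$mean_contact_duration_frames[m$action_type == "PC"]
  expect_gt(median(durIC), median(durPC))
  expect_gt(median(durIC), 10)
  expect_gt(mean(m$n_contacts[m$action_type == "IC"] > 0), 0.95)
})

test_that("cohort defaults reproduce the reactive/neoplastic contrast", {
  co <- simulateCohort(nMoviesPerGroup = 1, seed = 31)
  f <- motilityFeatures(co$tracks)
  spd <- tapply(f$speed_mean_um_per_min, f$diagnosis, mean)
  expect_gt(spd[["reactive"]], spd[["neoplastic"]])
  st <- contactStats(contactEvents(buildTemporalGraph(co$tracks, 7)),
                     co$tracks)
  af <- assembleFeatures(co$tracks, st)
  contacts <- tapply(af$n_contacts, af$diagnosis, mean)
  expect_gt(contacts[["reactive"]], contacts[["neoplastic"]])
  # metadata resolves every movie exactly once
  info <- trackInfo(co$tracks)
  key <- unique(paste(info$case_id, info$movie_id))
  expect_setequal(key, paste(co$metadata$case_id, co$metadata$movie_id))
})

test_that("scenario YAML round-trips into an equivalent config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "nFrames: 20",
    "frameIntervalMin: 0.5",
    "seed: 3",
    "diagnosis: reactive",
    "combos:",
    "  - {marker: CD20, track_type: LM, action_type: PC, n: 4}",
    "  - {marker: PD1, track_type: MT, action_type: AC, n: 2}"), f)
  sc <- readScenario(f)
  expect_s3_class(sc, "ScenarioConfig")
  sim <- simulateMovie(sc)
  expect_equal(nTracks(sim$tracks), 6)
  expect_equal(unique(trackPoints(sim$tracks)$diagnosis), "reactive")
})
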