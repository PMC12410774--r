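makeLabeledFeatures <- function() {
  sim <- simulateMovie(scenarioConfig(seed = 14, nFrames = 24))
  st <- contactStats(contactEvents(buildTemporalGraph(sim$tracks, 7)),
                     sim$tracks)
  list(features = assembleFeatures(sim$tracks, st), labels = sim$labels)
}

test_that("proportions reproduce a hand-counted group", {
  f <- data.frame(track_id = c("a", "b", "c", "d"), marker = "CD20",
                  case_id = "c1", movie_id = "m1", diagnosis = "reactive",
                  speed_mean_um_per_min = c(1, 1, 2, 6),
                  n_contacts = 0L, mean_contact_duration_frames = 0)
  lab <- data.frame(track_id = c("a", "b", "c", "d"),
                    track_type = c("LM", "LM", "MT", "LD"),
                    action_type = c("PC", "PC", "IC", "AC"))
  s <- summarizeCohort(lab, f)
  tab <- summaryTable(s)
  tt <- tab[tab$task == "track_type", ]
  expect_equal(tt$proportion[match(c("LM", "MT", "LD"), tt$class)],
               c(0.5, 0.25, 0.25))
  expect_equal(unique(tt$n_tracks), 4L)
  expect_equal(unique(tt$mean_speed_um_per_min), 2.5)

  # single-track group: one class gets proportion 1
  s1 <- summarizeCohort(lab[4, ], f[4, ])
  t1 <- summaryTable(s1)
  expect_equal(sum(t1$proportion[t1$task == "track_type"] == 1), 1)
})

test_that("group proportions always sum to one", {
  lf <- makeLabeledFeatures()
  s <- summarizeCohort(lf$labels, lf$features)
  tab <- summaryTable(s)
  grp <- paste(tab$diagnosis, tab$marker, tab$task)
  sums <- tapply(tab$proportion, grp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(validObject(s))
  # track counts are conserved per (marker, task) slice
  perGroup <- tab[tab$task == "track_type" & tab$class == "LM", ]
  expect_equal(sum(perGroup$n_tracks), nrow(lf$features))
})

test_that("metadata resolution overrides diagnosis and flags orphans", {
  lf <- makeLabeledFeatures()
  meta <- data.frame(case_id = "case1", movie_id = "movie1",
                     diagnosis = "FL")
  s <- summarizeCohort(lf$labels, lf$features, metadata = meta)
  expect_equal(unique(trackData(s)$diagnosis), "FL")
  badMeta <- data.frame(case_id = "other", movie_id = "movie9",
                        diagnosis = "FL")
  expect_error(summarizeCohort(lf$labels, lf$features, metadata = badMeta),
               "no metadata row")
  # declared-but-empty diagnosis groups stay in the table with NA proportions
  meta2 <- rbind(meta, data.frame(case_id = "c9", movie_id = "m9",
                                  diagnosis = "DLBCL"))
  s2 <- summarizeCohort(lf$labels, lf$features, metadata = meta2)
  tab2 <- summaryTable(s2)
  expect_true(any(tab2$diagnosis == "DLBCL" & tab2$n_tracks == 0))
})

test_that("a group compared with itself shows zero differences", {
  lf <- makeLabeledFeatures()
  s <- summarizeCohort(lf$labels, lf$features)
  cmp <- compareGroups(s, "unspecified", "unspecified", nBoot = 50, seed = 3)
  expect_true(all(cmp$estimate == 0))
  expect_error(compareGroups(s, "unspecified", "nosuch"), "unknown group")
})

test_that("bootstrap intervals are seeded and reproducible", {
  co <- simulateCohort(nMoviesPerGroup = 1, seed = 8, nFrames = 24)
  st <- contactStats(contactEvents(buildTemporalGraph(co$tracks, 7)),
                     co$tracks)
  f <- assembleFeatures(co$tracks, st)
  s <- summarizeCohort(co$labels, f, metadata = co$metadata)
  c1 <- compareGroups(s, "neoplastic", "reactive", nBoot = 80, seed = 9)
  c2 <- compareGroups(s, "neoplastic", "reactive", nBoot = 80, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$ci_lo <= c1$estimate & c1$estimate <= c1$ci_hi))
  # generative ordering: more LM/PC and slower in the neoplastic group
  est <- setNames(c1$estimate, c1$quantity)
  expect_gt(est[["prop_LM"]], 0)
  expect_gt(est[["prop_PC"]], 0)
  expect_lt(est[["mean_speed_um_per_min"]], 0)
})
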