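test_that("assembleFeatures joins motility and contact features", {
  ts <- pairContactSet(2:5)
  st <- contactStats(contactEvents(buildTemporalGraph(ts, 7)), ts)
  f <- assembleFeatures(ts, st)
  expect_equal(nrow(f), 2)
  want <- c("displacement_length_um", "track_length_um",
            "speed_mean_um_per_min", "straightness", "intensity_mean",
            "n_contacts", "mean_contact_duration_frames")
  expect_identical(tail(names(f), 7), want)     # stable column order
  expect_error(assembleFeatures(ts, st[st$track_id != "b", ]),
               "missing contact stats")
})

test_that("an isolated stationary track has zero speed and no contacts", {
  still <- trackFromCoords(matrix(0, 6, 3), id = "still")
  far <- trackFromCoords(matrix(100, 6, 3), id = "far")
  ts <- TrackSet(rbind(still, far), 1)
  f <- assembleFeatures(ts, contactStats(
    contactEvents(buildTemporalGraph(ts, 7)), ts))
  row <- f[f$track_id == "still", ]
  expect_equal(row$speed_mean_um_per_min, 0)
  expect_equal(row$n_contacts, 0L)
  expect_equal(row$mean_contact_duration_frames, 0)
})

test_that("cross-validation is deterministic and seed-sensitive", {
  f <- toyFeatureTable()
  a <- crossValidate(f, task = "track_type", nRepeats = 3, seed = 5)
  b <- crossValidate(f, task = "track_type", nRepeats = 3, seed = 5)
  expect_identical(a@accuracies, b@accuracies)
  expect_identical(confusionMatrix(a), confusionMatrix(b))
  expect_true(all(a@accuracies >= 0 & a@accuracies <= 1))
  expect_equal(sum(confusionMatrix(a)), 3 * nrow(f))  # rows sum to supports
})

test_that("well-separated classes are recovered almost perfectly", {
  f <- toyFeatureTable()
  cv <- crossValidate(f, task = "track_type", nRepeats = 5, seed = 2)
  expect_gte(meanAccuracy(cv), 0.95)
  cva <- crossValidate(f, task = "action_type", nRepeats = 5, seed = 2)
  expect_gte(meanAccuracy(cva), 0.95)
})

test_that("a class with fewer samples than folds is a named error", {
  f <- toyFeatureTable(nPerClass = 12)
  f <- f[!(f$tracktype == "LD" & seq_len(nrow(f)) %% 4 != 0), ]
  expect_error(crossValidate(f, task = "track_type", nFolds = 5, seed = 1),
               "LD")
})

test_that("training stores schema and survives a save/load round-trip", {
  f <- toyFeatureTable()
  model <- trainBehaviorModel(f, seed = 9)
  expect_s4_class(model, "BehaviorModel")
  p1 <- predictBehavior(model, f)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  p2 <- predictBehavior(readRDS(path), f)
  expect_identical(p1, p2)
  # training accuracy should not be worse than CV accuracy on the same data
  trainAcc <- mean(p1$track_type == f$tracktype)
  cvAcc <- meanAccuracy(crossValidate(f, task = "track_type",
                                      nRepeats = 3, seed = 9))
  expect_gte(trainAcc, cvAcc - 1e-9)
})

test_that("prediction validates its inputs", {
  f <- toyFeatureTable()
  model <- trainBehaviorModel(f, seed = 9)
  expect_error(predictBehavior(model, f[setdiff(names(f), "straightness")]),
               "schema")
  fna <- f; fna$n_contacts[3] <- NA
  expect_error(predictBehavior(model, fna), "finite")
  expect_error(trainBehaviorModel(f[f$tracktype == "LM", ]),
               "at least 2 classes")
  # duplicated rows get identical predictions
  dup <- rbind(f, f)
  dup$track_id <- sprintf("r%03d", seq_len(nrow(dup)))
  pd <- predictBehavior(model, dup)
  expect_identical(pd$track_type[seq_len(nrow(f))],
                   pd$track_type[nrow(f) + seq_len(nrow(f))])
})

test_that("permuted labels drop accuracy to chance", {
  f <- toyFeatureTable(nPerClass = 25)
  set.seed(123)
  f$tracktype <- sample(f$tracktype)
  cv <- crossValidate(f, task = "track_type", nRepeats = 6, seed = 4)
  guard <- max(3 * sdAccuracy(cv), 0.12)   # small-n sampling error floor
  expect_lt(abs(meanAccuracy(cv) - 1 / 3), guard)
})

test_that("increasing archetype overlap never improves accuracy", {
  accs <- vapply(c(0, 0.7, 0.95), function(ov) {
    sim <- simulateScenarioSet(nMovies = 1, seed = 17, overlap = ov,
                               nFrames = 30)
    st <- contactStats(contactEvents(buildTemporalGraph(sim$tracks, 7)),
                       sim$tracks)
    f <- assembleFeatures(sim$tracks, st)
    cv <- crossValidate(f, sim$labels, task = "track_type",
                        nRepeats = 3, seed = 8)
    median(cv@accuracies)
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})

test_that("label comparison reports per-task agreement", {
  pred <- data.frame(track_id = c("a", "b", "c"),
                     track_type = c("LM", "MT", "LD"),
                     action_type = c("PC", "IC", "AC"))
  ref <- data.frame(track_id = c("c", "a", "b"),
                    track_type = c("LD", "LM", "LM"),
                    action_type = c("AC", "PC", "IC"))
  rep <- compareLabels(pred, ref)
  expect_equal(rep$track_type$accuracy, 2 / 3)
  expect_equal(rep$action_type$accuracy, 1)
  expect_equal(sum(rep$track_type$confusion), 3)
})
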