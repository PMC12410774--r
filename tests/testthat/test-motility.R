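test_that("displacement, length and straightness match hand-computed tracks", {
  # 3-4-5 triangle
  ts <- trackSetFromCoords(trackFromCoords(rbind(c(0, 0, 0), c(3, 4, 0))))
  expect_equal(unname(displacementLength(ts)), 5)

  # diagonal step (1,1,1) -> (2,3,5)
  ts <- trackSetFromCoords(trackFromCoords(rbind(c(1, 1, 1), c(2, 3, 5))))
  expect_equal(unname(displacementLength(ts)), sqrt(21))

  # L-shaped track: legs 3 and 4
  L <- trackSetFromCoords(
    trackFromCoords(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))))
  expect_equal(unname(trackLength(L)), 7)
  expect_equal(unname(displacementLength(L)), 5)
  expect_equal(unname(straightness(L)), 5 / 7, tolerance = 1e-9)

  # square loop of side 2: perimeter 8, returns to start
  sq <- trackSetFromCoords(trackFromCoords(
    rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0), c(0, 0, 0))))
  expect_equal(unname(trackLength(sq)), 8)
  expect_equal(unname(displacementLength(sq)), 0)
  expect_equal(unname(straightness(sq)), 0)
})

test_that("mean speed averages per-step speeds", {
  # steps of 2 um then 4 um, 1 min each -> mean 3 um/min
  ts <- trackSetFromCoords(
    trackFromCoords(rbind(c(0, 0, 0), c(2, 0, 0), c(6, 0, 0))))
  expect_equal(unname(speedMean(ts)), 3)

  # stationary track
  st <- trackSetFromCoords(trackFromCoords(matrix(1, 4, 3)))
  expect_equal(unname(speedMean(st)), 0)
  expect_equal(unname(straightness(st)), 0)   # zero path length convention

  # uniform sampling: mean step speed == length / duration
  set.seed(11)
  rs <- TrackSet(randomTrackTable(20, nFrames = 9), 1)
  expect_equal(unname(speedMean(rs)),
               unname(trackLength(rs) / trackDurations(rs)),
               tolerance = 1e-9)
})

test_that("intensity mean is the arithmetic per-point mean", {
  df <- trackFromCoords(matrix(runif(12), 4, 3), intensity = c(1, 2, 3, 4))
  expect_equal(unname(intensityMean(TrackSet(df, 1))), 2.5)
  df2 <- trackFromCoords(matrix(runif(6), 2, 3), intensity = c(0, 10))
  expect_equal(unname(intensityMean(TrackSet(df2, 1))), 5)
})

test_that("feature invariants hold on random tracks", {
  set.seed(23)
  ts <- TrackSet(randomTrackTable(300, nFrames = 8), 1)
  disp <- displacementLength(ts)
  len <- trackLength(ts)
  str <- straightness(ts)
  expect_true(all(disp <= len + 1e-9))
  expect_true(all(str >= 0 & str <= 1))
  expect_true(all(is.finite(c(disp, len, str, speedMean(ts)))))

  # rigid translation leaves all motility features unchanged
  p <- trackPoints(ts)
  p$x_um <- p$x_um + 123.4; p$y_um <- p$y_um - 77; p$z_um <- p$z_um + 5.5
  shifted <- TrackSet(p, 1)
  expect_equal(displacementLength(shifted), disp, tolerance = 1e-9)
  expect_equal(trackLength(shifted), len, tolerance = 1e-9)
  expect_equal(straightness(shifted), str, tolerance = 1e-9)
})

test_that("time reversal preserves displacement, length and straightness", {
  set.seed(31)
  tab <- randomTrackTable(50, nFrames = 7)
  ts <- TrackSet(tab, 1)
  rev_tab <- do.call(rbind, lapply(split(tab, tab$track_id), function(d) {
    d[c("x_um", "y_um", "z_um")] <- d[rev(seq_len(nrow(d))),
                                      c("x_um", "y_um", "z_um")]
    d
  }))
  tsr <- TrackSet(rev_tab, 1)
  expect_equal(displacementLength(tsr), displacementLength(ts),
               tolerance = 1e-9)
  expect_equal(trackLength(tsr), trackLength(ts), tolerance = 1e-9)
  expect_equal(straightness(tsr), straightness(ts), tolerance = 1e-9)
})

test_that("motilityFeatures returns one row per track with the 5 features", {
  set.seed(5)
  ts <- TrackSet(randomTrackTable(6, nFrames = 5), 1)
  f <- motilityFeatures(ts)
  expect_equal(nrow(f), 6)
  expect_true(all(c("displacement_length_um", "track_length_um",
                    "speed_mean_um_per_min", "straightness",
                    "intensity_mean") %in% names(f)))
  expect_equal(f$straightness,
               unname(straightness(ts)[f$track_id]), tolerance = 1e-12)
})
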