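# Fixture builders shared across test files. All fixtures are generated in
# code; no data files on disk.

# one track from a coordinate matrix (rows = frames)
trackFromCoords <- function(coords, id = "t1", intensity = 1,
                            marker = "CD20", frameInterval = 1,
                            frames = seq_len(nrow(coords)) - 1L) {
  coords <- as.matrix(coords)
  data.frame(track_id = id, frame = frames,
             time_min = frames * frameInterval,
             x_um = coords[, 1], y_um = coords[, 2], z_um = coords[, 3],
             intensity = rep_len(intensity, nrow(coords)),
             marker = marker, stringsAsFactors = FALSE)
}

trackSetFromCoords <- function(..., frameInterval = 1) {
  TrackSet(do.call(rbind, list(...)), frameIntervalMin = frameInterval)
}

# random multi-track point table (valid by construction)
randomTrackTable <- function(nTracks, nFrames = 8, frameInterval = 1,
                             spread = 20) {
  do.call(rbind, lapply(seq_len(nTracks), function(i) {
    coords <- matrix(stats::runif(nFrames * 3, 0, spread), nFrames, 3)
    trackFromCoords(coords, id = sprintf("rt%04d", i),
                    intensity = stats::runif(nFrames, 0, 50),
                    marker = sample(c("CD20", "PD1"), 1),
                    frameInterval = frameInterval)
  }))
}

# independent all-pairs contact oracle: full n x n distance matrix via outer
# sums (different route than the package's dist()-based construction)
bruteForceEdges <- function(tracks, radius) {
  p <- trackPoints(tracks)
  movie <- paste(p$case_id, p$movie_id, sep = "/")
  out <- list()
  for (mv in unique(movie)) {
    pm <- p[movie == mv, ]
    for (fr in sort(unique(pm$frame))) {
      q <- pm[pm$frame == fr, ]
      n <- nrow(q)
      if (n < 2) next
      d2 <- outer(q$x_um, q$x_um, "-")^2 + outer(q$y_um, q$y_um, "-")^2 +
            outer(q$z_um, q$z_um, "-")^2
      hit <- which(upper.tri(d2) & sqrt(d2) <= radius, arr.ind = TRUE)
      if (!nrow(hit)) next
      a <- q$track_id[hit[, 1]]; b <- q$track_id[hit[, 2]]
      out[[length(out) + 1]] <- data.frame(
        movie_id = mv, frame = fr,
        track_a = pmin(a, b), track_b = pmax(a, b),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(movie_id = character(0), frame = integer(0),
                      track_a = character(0), track_b = character(0)))
  e <- do.call(rbind, out)
  e[order(e$movie_id, e$frame, e$track_a, e$track_b), ]
}

edgeKey <- function(e) paste(e$movie_id, e$frame, e$track_a, e$track_b)

# hand-placed two-track set where the pair sits within `radius` exactly at
# `contactFrames`, far apart otherwise
pairContactSet <- function(contactFrames, nFrames = 8, gapDist = 50) {
  frames <- 0:(nFrames - 1)
  x2 <- ifelse(frames %in% contactFrames, 3, gapDist)
  a <- trackFromCoords(cbind(0, 0, 0)[rep(1, nFrames), , drop = FALSE],
                       id = "a", frames = frames)
  b <- trackFromCoords(cbind(x2, 0, 0), id = "b", frames = frames)
  # keep time strictly increasing despite constant coords
  TrackSet(rbind(a, b), frameIntervalMin = 1)
}

# small labeled feature table for classifier tests: three well separated
# blobs per task
toyFeatureTable <- function(nPerClass = 20, seed = 42) {
  set.seed(seed)
  mk <- function(cls, act, disp, len, speed, str, inten, nc, dur) {
    n <- nPerClass
    data.frame(
      track_id = sprintf("%s_%s_%03d", cls, act, seq_len(n)),
      marker = "CD20", case_id = "c1", movie_id = "m1",
      diagnosis = "unspecified",
      tracktype = cls, actiontype = act,
      displacement_length_um = stats::rnorm(n, disp, disp * 0.1 + 0.1),
      track_length_um = stats::rnorm(n, len, len * 0.1 + 0.1),
      speed_mean_um_per_min = abs(stats::rnorm(n, speed, 0.2)),
      straightness = pmin(pmax(stats::rnorm(n, str, 0.05), 0), 1),
      intensity_mean = stats::rnorm(n, inten, 5),
      n_contacts = nc + stats::rpois(n, 0.2),
      mean_contact_duration_frames = abs(stats::rnorm(n, dur, dur * 0.1 + 0.1)),
      stringsAsFactors = FALSE)
  }
  rbind(mk("LM", "PC", 1, 5, 0.5, 0.1, 100, 0, 0),
        mk("MT", "IC", 5, 40, 2.5, 0.12, 100, 3, 30),
        mk("LD", "AC", 60, 80, 6, 0.85, 100, 1, 2))
}
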