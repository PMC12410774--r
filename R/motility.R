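## Per-track motility features matching the standard spot-tracking export:
## Track Displacement Length, Track Length, Track Speed Mean, Track
## Straightness, Track Intensity Mean.

.stepTable <- function(p) {
  ## consecutive observed steps within each track; p assumed ordered
  n <- nrow(p)
  if (n < 2L) {
    return(data.frame(track_id = character(0), len_um = numeric(0),
                      dt_min = numeric(0)))
  }
  same <- p$track_id[-1L] == p$track_id[-n]
  dx <- diff(p$x_um); dy <- diff(p$y_um); dz <- diff(p$z_um)
  data.frame(track_id = p$track_id[-n][same],
             len_um = sqrt(dx^2 + dy^2 + dz^2)[same],
             dt_min = diff(p$time_min)[same])
}

.perTrackFactor <- function(x) {
  p <- x@points
  factor(p$track_id, levels = unique(p$track_id))
}

#' Track displacement length
#'
#' Euclidean 3D distance (micrometers) between a track's first and last
#' observed point.
#'
#' @param x a \linkS4class{TrackSet}.
#' @return Named numeric vector, one value per track.
#' @export
displacementLength <- function(x) {
  stopifnot(is(x, "TrackSet"))
  p <- x@points
  f <- .perTrackFactor(x)
  first <- !duplicated(p$track_id)
  last <- !duplicated(p$track_id, fromLast = TRUE)
  d <- sqrt((p$x_um[last] - p$x_um[first])^2 +
            (p$y_um[last] - p$y_um[first])^2 +
            (p$z_um[last] - p$z_um[first])^2)
  stats::setNames(d, levels(f))
}

#' Track length
#'
#' Sum of Euclidean step lengths (micrometers) over consecutive observed
#' points; internal frame gaps contribute a single straight-line step.
#'
#' @inheritParams displacementLength
#' @return Named numeric vector, one value per track.
#' @export
trackLength <- function(x) {
  stopifnot(is(x, "TrackSet"))
  steps <- .stepTable(x@points)
  ids <- unique(x@points$track_id)
  len <- tapply(steps$len_um, factor(steps$track_id, levels = ids), sum)
  stats::setNames(as.numeric(len), ids)
}

#' Track mean speed
#'
#' Mean of per-step instantaneous speeds (step length over step time,
#' micrometers per minute). Under uniform sampling this equals track length
#' divided by track duration.
#'
#' @inheritParams displacementLength
#' @return Named numeric vector, one value per track.
#' @export
speedMean <- function(x) {
  stopifnot(is(x, "TrackSet"))
  steps <- .stepTable(x@points)
  ids <- unique(x@points$track_id)
  sp <- tapply(steps$len_um / steps$dt_min,
               factor(steps$track_id, levels = ids), mean)
  stats::setNames(as.numeric(sp), ids)
}

#' Track straightness
#'
#' Ratio of displacement length to track length, in [0, 1]; defined as 0
#' for a track of zero path length (a perfectly stationary cell).
#'
#' @inheritParams displacementLength
#' @return Named numeric vector, one value per track.
#' @export
straightness <- function(x) {
  stopifnot(is(x, "TrackSet"))
  len <- trackLength(x)
  disp <- displacementLength(x)
  out <- ifelse(len > 0, disp / len, 0)
  ## guard against displacement/length > 1 by floating-point rounding
  pmin(out, 1)
}

#' Track mean intensity
#'
#' Arithmetic mean of per-point spot intensity (arbitrary units).
#'
#' @inheritParams displacementLength
#' @return Named numeric vector, one value per track.
#' @export
intensityMean <- function(x) {
  stopifnot(is(x, "TrackSet"))
  f <- .perTrackFactor(x)
  stats::setNames(as.numeric(tapply(x@points$intensity, f, mean)), levels(f))
}

#' Per-track motility feature table
#'
#' Computes the five per-track motility/intensity features for every track:
#' displacement length, track length, mean speed, straightness and mean
#' intensity, alongside track metadata (and label columns when present).
#' Contact features are appended separately from the temporal cell graph
#' (see \code{\link{assembleFeatures}}).
#'
#' @inheritParams displacementLength
#' @return data.frame, one row per track: metadata columns plus
#'   \code{displacement_length_um}, \code{track_length_um},
#'   \code{speed_mean_um_per_min}, \code{straightness},
#'   \code{intensity_mean}.
#' @export
motilityFeatures <- function(x) {
  stopifnot(is(x, "TrackSet"))
  info <- trackInfo(x)
  if (!nrow(info)) {
    out <- cbind(info,
                 data.frame(displacement_length_um = numeric(0),
                            track_length_um = numeric(0),
                            speed_mean_um_per_min = numeric(0),
                            straightness = numeric(0),
                            intensity_mean = numeric(0)))
    return(out)
  }
  out <- info
  out$displacement_length_um <- unname(displacementLength(x)[info$track_id])
  out$track_length_um <- unname(trackLength(x)[info$track_id])
  out$speed_mean_um_per_min <- unname(speedMean(x)[info$track_id])
  out$straightness <- unname(straightness(x)[info$track_id])
  out$intensity_mean <- unname(intensityMean(x)[info$track_id])
  out
}
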