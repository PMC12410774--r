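#' Ensemble time-averaged mean squared displacement
#'
#' For each lag of 1..\code{maxLagFrames} frames, computes the time-averaged
#' MSD per track over all overlapping start points (all pairs of observed
#' frames exactly the lag apart; frame gaps simply contribute no pair), then
#' averages across tracks. RMSD is the elementwise square root. Lag times
#' assume uniform sampling at the TrackSet's frame interval.
#'
#' @param x a \linkS4class{TrackSet}, uniformly sampled.
#' @param maxLagFrames largest lag in frames; must be smaller than the
#'   shortest track's frame span.
#' @return An \linkS4class{MSDCurve}.
#' @export
computeMSD <- function(x, maxLagFrames) {
  stopifnot(is(x, "TrackSet"))
  p <- x@points
  if (!nrow(p)) stop("empty TrackSet", call. = FALSE)
  maxLagFrames <- as.integer(maxLagFrames)
  if (length(maxLagFrames) != 1L || is.na(maxLagFrames) || maxLagFrames < 1L)
    stop("maxLagFrames must be a positive integer", call. = FALSE)
  span <- tapply(p$frame, p$track_id, function(f) max(f) - min(f))
  if (maxLagFrames >= min(span))
    stop(sprintf(
      "maxLagFrames (%d) must be smaller than the shortest track's frame span (%d)",
      maxLagFrames, min(span)), call. = FALSE)

  byTrack <- split(p[c("frame", "x_um", "y_um", "z_um")], p$track_id)
  lags <- seq_len(maxLagFrames)
  perTrack <- vapply(byTrack, function(tp) {
    idx <- match(tp$frame + rep(lags, each = nrow(tp)), tp$frame)
    i0 <- rep(seq_len(nrow(tp)), times = maxLagFrames)
    lag <- rep(lags, each = nrow(tp))
    ok <- !is.na(idx)
    sq <- (tp$x_um[idx[ok]] - tp$x_um[i0[ok]])^2 +
          (tp$y_um[idx[ok]] - tp$y_um[i0[ok]])^2 +
          (tp$z_um[idx[ok]] - tp$z_um[i0[ok]])^2
    out <- tapply(sq, factor(lag[ok], levels = lags), mean)
    as.numeric(out)
  }, numeric(maxLagFrames))
  perTrack <- matrix(perTrack, nrow = maxLagFrames)
  msd <- rowMeans(perTrack, na.rm = TRUE)
  new("MSDCurve",
      lagsFrames = lags,
      lagsMin = lags * x@frameIntervalMin,
      msdUm2 = msd,
      rmsdUm = sqrt(msd),
      nTracks = length(byTrack))
}

#' @describeIn accessors MSD curve as a data.frame (lag_frames, lag_min,
#'   msd_um2, rmsd_um).
#' @export
setMethod("msdTable", "MSDCurve", function(x) {
  data.frame(lag_frames = x@lagsFrames, lag_min = x@lagsMin,
             msd_um2 = x@msdUm2, rmsd_um = x@rmsdUm)
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lag(s) over %d track(s), lag step %g min\n",
              length(object@lagsFrames), object@nTracks,
              if (length(object@lagsMin)) object@lagsMin[1L] else NA_real_))
  invisible(NULL)
})

#' Anomalous-diffusion exponent from an MSD curve
#'
#' Least-squares slope of log(MSD) versus log(lag time) over the first
#' \code{fitFraction} of lags. The slope (commonly written alpha) is about 2
#' for ballistic motion, about 1 for Brownian diffusion and below 1 for
#' confined/subdiffusive motion; fitting only small lags avoids the noisy,
#' poorly averaged long-lag tail (set \code{fitFraction = 1} to fit the whole
#' curve, e.g. to detect the MSD plateau of strongly confined motion).
#'
#' @param curve an \linkS4class{MSDCurve}.
#' @param fitFraction fraction (0, 1] of the smallest lags used (default
#'   0.25); at least 3 lags are always used.
#' @return The fitted exponent (single numeric).
#' @export
fitAlpha <- function(curve, fitFraction = 0.25) {
  stopifnot(is(curve, "MSDCurve"))
  if (length(fitFraction) != 1L || !is.finite(fitFraction) ||
      fitFraction <= 0 || fitFraction > 1)
    stop("fitFraction must be in (0, 1]", call. = FALSE)
  k <- max(3L, ceiling(fitFraction * length(curve@lagsFrames)))
  k <- min(k, length(curve@lagsFrames))
  msd <- curve@msdUm2[seq_len(k)]
  tau <- curve@lagsMin[seq_len(k)]
  if (k < 3L)
    stop("need at least 3 lags in the fitted range", call. = FALSE)
  if (any(msd <= 0))
    stop("zero MSD in the fit range: the tracks are stationary at some lag; ",
         "widen the lag range or check the input", call. = FALSE)
  unname(stats::coef(stats::lm(log(msd) ~ log(tau)))[2L])
}
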