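#' @import methods
NULL

## Column schema shared by the reader, writer and validity methods.
.TRACK_REQUIRED_COLS <- c("track_id", "frame", "time_min",
                          "x_um", "y_um", "z_um", "intensity", "marker")
.TRACK_META_COLS  <- c("case_id", "movie_id", "diagnosis")
.TRACK_LABEL_COLS <- c("tracktype", "actiontype")

.TRACK_TYPES  <- c("LM", "MT", "LD")
.ACTION_TYPES <- c("PC", "IC", "AC")

#' TrackSet: 4D cell tracks for one or more co-analyzed movies
#'
#' A \code{TrackSet} holds per-frame 3D centroid samples for a collection of
#' tracked cells, at the granularity of a spot-tracking export: one row per
#' (track, frame) with coordinates in micrometers, acquisition time in
#' minutes, spot intensity, and the staining marker (\code{CD20} for B cells,
#' \code{PD1} for T cells, or user-defined). Provenance columns
#' (\code{case_id}, \code{movie_id}, \code{diagnosis}) tie each track to a
#' cohort; optional \code{tracktype}/\code{actiontype} columns carry
#' ground-truth or predicted behavior labels.
#'
#' Validity requires: at least two points per track, no duplicated
#' (track_id, frame), strictly increasing time within each track, finite
#' coordinates, non-negative intensity, and constant per-track metadata.
#' All tracks share one frame interval (the movie sampling step, minutes);
#' internal frame gaps are permitted and are never interpolated.
#'
#' @slot points data.frame of per-frame samples, ordered by (track_id, frame).
#' @slot frameIntervalMin single positive numeric, movie sampling step in
#'   minutes.
#' @exportClass TrackSet
setClass("TrackSet",
  representation(points = "data.frame", frameIntervalMin = "numeric"))

setValidity("TrackSet", function(object) {
  p <- object@points
  msgs <- character()
  miss <- setdiff(c(.TRACK_REQUIRED_COLS, .TRACK_META_COLS), names(p))
  if (length(miss))
    return(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  if (length(object@frameIntervalMin) != 1L ||
      !is.finite(object@frameIntervalMin) || object@frameIntervalMin <= 0)
    msgs <- c(msgs, "frameIntervalMin must be a single positive number")
  if (nrow(p) == 0L) return(if (length(msgs)) msgs else TRUE)

  num_cols <- c("frame", "time_min", "x_um", "y_um", "z_um", "intensity")
  for (cc in num_cols)
    if (!is.numeric(p[[cc]]) || any(!is.finite(p[[cc]])))
      msgs <- c(msgs, sprintf("column '%s' must be finite numeric", cc))
  if (length(msgs)) return(msgs)
  if (any(p$frame < 0) || any(p$frame != round(p$frame)))
    msgs <- c(msgs, "frame must be a non-negative integer index")
  if (any(p$intensity < 0))
    msgs <- c(msgs, "intensity must be >= 0")

  id <- p$track_id
  if (anyDuplicated(paste(id, p$frame, sep = "\r")))
    msgs <- c(msgs, "duplicated (track_id, frame) pair")

  ## points are stored sorted by (track_id, frame); enforce and use it
  o <- order(id, p$frame)
  if (!identical(o, seq_len(nrow(p))))
    msgs <- c(msgs, "points must be ordered by (track_id, frame)")
  same <- id[-1L] == id[-length(id)]
  if (any(same & diff(p$time_min) <= 0))
    msgs <- c(msgs, "time_min must strictly increase with frame within a track")
  if (any(tabulate(factor(id)) < 2L))
    msgs <- c(msgs, "every track needs >= 2 points")
  for (cc in c("marker", .TRACK_META_COLS)) {
    n_per <- vapply(split(p[[cc]], id), function(v) length(unique(v)), 1L)
    if (any(n_per != 1L))
      msgs <- c(msgs, sprintf("column '%s' must be constant within a track", cc))
  }
  if (length(msgs)) msgs else TRUE
})

#' TemporalCellGraph: per-frame unit-disc proximity graphs
#'
#' A temporal cell graph is a sequence of unit-disc graphs, one per movie
#' frame: nodes are the tracks observed at that frame, and an undirected edge
#' joins two cells whose centroids lie within the contact radius (inclusive).
#' Edges are only formed between tracks of the same movie (co-imaged cells)
#' and connect any marker pair. Pairs are stored canonically with
#' \code{track_a < track_b}.
#'
#' @slot nodes data.frame (movie_id, frame, track_id): track presence per frame.
#' @slot edges data.frame (movie_id, frame, track_a, track_b, distance_um).
#' @slot radiusUm contact radius in micrometers (default 7).
#' @exportClass TemporalCellGraph
setClass("TemporalCellGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 radiusUm = "numeric"))

setValidity("TemporalCellGraph", function(object) {
  e <- object@edges
  n <- object@nodes
  msgs <- character()
  if (length(object@radiusUm) != 1L || !is.finite(object@radiusUm) ||
      object@radiusUm <= 0)
    msgs <- c(msgs, "radiusUm must be a single positive number")
  if (!all(c("movie_id", "frame", "track_id") %in% names(n)))
    return("nodes needs columns movie_id, frame, track_id")
  if (!all(c("movie_id", "frame", "track_a", "track_b", "distance_um")
           %in% names(e)))
    return("edges needs columns movie_id, frame, track_a, track_b, distance_um")
  if (nrow(e)) {
    if (any(e$track_a == e$track_b))
      msgs <- c(msgs, "self-loop edge found")
    if (any(e$track_a > e$track_b))
      msgs <- c(msgs, "edges must be stored with track_a < track_b")
    if (any(e$distance_um > object@radiusUm + 1e-9))
      msgs <- c(msgs, "edge longer than the contact radius")
    key <- function(m, f, t) paste(m, f, t, sep = "\r")
    present <- key(n$movie_id, n$frame, n$track_id)
    if (!all(key(e$movie_id, e$frame, e$track_a) %in% present) ||
        !all(key(e$movie_id, e$frame, e$track_b) %in% present))
      msgs <- c(msgs, "edge endpoint absent from that frame's node set")
  }
  if (length(msgs)) msgs else TRUE
})

#' MSDCurve: ensemble time-averaged mean squared displacement
#'
#' Per-lag mean squared displacement (micrometers squared) and its square
#' root, computed per track over all overlapping start points and then
#' averaged across tracks. Lags start at one frame interval. The log-log
#' slope over small lags (see \code{\link{fitAlpha}}) is the
#' anomalous-diffusion exponent: about 1 for Brownian motion, about 2 for
#' ballistic (directed) motion, below 1 for confined/subdiffusive motion.
#'
#' @slot lagsFrames integer lags in frames, strictly increasing from 1.
#' @slot lagsMin lag times in minutes.
#' @slot msdUm2 MSD per lag.
#' @slot rmsdUm elementwise square root of \code{msdUm2}.
#' @slot nTracks number of tracks that entered the ensemble average.
#' @exportClass MSDCurve
setClass("MSDCurve",
  representation(lagsFrames = "integer", lagsMin = "numeric",
                 msdUm2 = "numeric", rmsdUm = "numeric", nTracks = "integer"))

setValidity("MSDCurve", function(object) {
  msgs <- character()
  k <- length(object@lagsFrames)
  if (length(object@lagsMin) != k || length(object@msdUm2) != k ||
      length(object@rmsdUm) != k)
    return("lag, MSD and RMSD vectors must have equal length")
  if (k) {
    if (object@lagsFrames[1L] < 1L || any(diff(object@lagsFrames) <= 0))
      msgs <- c(msgs, "lags must strictly increase, starting at >= 1 frame")
    if (any(object@msdUm2 < 0))
      msgs <- c(msgs, "MSD must be non-negative")
    if (any(abs(object@rmsdUm - sqrt(object@msdUm2)) > 1e-9))
      msgs <- c(msgs, "RMSD must equal sqrt(MSD) elementwise")
  }
  if (length(msgs)) msgs else TRUE
})

#' BehaviorModel: paired random forests for track and action types
#'
#' Bundles two independently trained random-forest classifiers — one for the
#' track-type task (LM/MT/LD) and one for the action-type task (PC/IC/AC) —
#' together with the feature schema (the 7 training features in fixed order),
#' the training seed and the forest hyperparameters. Prediction is
#' deterministic given a stored model; ties in predicted class probability
#' are broken by the fixed class orders LM < MT < LD and PC < IC < AC.
#'
#' @slot trackForest,actionForest fitted \pkg{randomForest} objects.
#' @slot featureNames character(7), the feature schema in training order.
#' @slot seed integer training seed.
#' @slot trackClasses,actionClasses class vocabularies in tie-break order.
#' @slot hyperparameters list (ntree, mtry).
#' @exportClass BehaviorModel
setClass("BehaviorModel",
  representation(trackForest = "ANY", actionForest = "ANY",
                 featureNames = "character", seed = "integer",
                 trackClasses = "character", actionClasses = "character",
                 hyperparameters = "list"))

#' ValidationReport: repeated stratified cross-validation results
#'
#' Holds per-repeat hold-out accuracies of one classification task, the
#' pooled confusion matrix over all repeats and folds (rows = true class,
#' columns = predicted class), and per-class precision/recall.
#'
#' @slot task "track_type" or "action_type".
#' @slot accuracies numeric, one hold-out accuracy per CV repeat.
#' @slot confusion pooled confusion matrix (true x predicted).
#' @slot perClass data.frame (class, precision, recall, support).
#' @slot nRepeats,nFolds,seed CV configuration.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(task = "character", accuracies = "numeric",
                 confusion = "matrix", perClass = "data.frame",
                 nRepeats = "integer", nFolds = "integer", seed = "integer"))

setValidity("ValidationReport", function(object) {
  msgs <- character()
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msgs <- c(msgs, "accuracies must lie in [0, 1]")
  if (length(object@accuracies) != object@nRepeats)
    msgs <- c(msgs, "one accuracy per repeat required")
  if (length(msgs)) msgs else TRUE
})

#' CohortSummary: type distributions and motility per diagnosis group
#'
#' Per (diagnosis, marker, task) group: class proportions (summing to one
#' within the group), track count, mean and median speed, mean contact count
#' and mean contact duration. The per-track table behind the summary is kept
#' so group comparisons can bootstrap over tracks.
#'
#' @slot table summary data.frame (diagnosis, marker, task, class,
#'   proportion, n_tracks, plus group motility summaries).
#' @slot trackData per-track data.frame backing the summary.
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(table = "data.frame", trackData = "data.frame"))

setValidity("CohortSummary", function(object) {
  tab <- object@table
  if (nrow(tab)) {
    grp <- paste(tab$diagnosis, tab$marker, tab$task, sep = "\r")
    sums <- tapply(tab$proportion, grp, sum)
    ok <- is.na(sums) | abs(sums - 1) <= 1e-9
    if (!all(ok))
      return("class proportions must sum to 1 within each group")
  }
  TRUE
})
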