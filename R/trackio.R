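#' Construct a TrackSet from a per-point table
#'
#' Normalizes a raw per-point table into a valid \linkS4class{TrackSet}:
#' fills missing provenance columns with defaults, coerces types, orders
#' points by (track_id, frame), and drops tracks with fewer than two points
#' (a single-point track carries no motion information) with a warning.
#'
#' @param points data.frame with columns \code{track_id}, \code{frame},
#'   \code{time_min}, \code{x_um}, \code{y_um}, \code{z_um},
#'   \code{intensity}, \code{marker}; optional \code{case_id},
#'   \code{movie_id}, \code{diagnosis}, \code{tracktype}, \code{actiontype}.
#'   Extra columns are dropped.
#' @param frameIntervalMin movie sampling step in minutes (single positive
#'   number). Spot-tracking exports do not record it, so it must be supplied.
#' @return A \linkS4class{TrackSet}.
#' @export
TrackSet <- function(points, frameIntervalMin) {
  stopifnot(is.data.frame(points))
  miss <- setdiff(.TRACK_REQUIRED_COLS, names(points))
  if (length(miss))
    stop("track table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  p <- points
  defaults <- c(case_id = "case1", movie_id = "movie1",
                diagnosis = "unspecified")
  for (cc in names(defaults))
    if (is.null(p[[cc]])) p[[cc]] <- rep(defaults[[cc]], nrow(p))
  keep <- intersect(c(.TRACK_REQUIRED_COLS, .TRACK_META_COLS,
                      .TRACK_LABEL_COLS), names(p))
  p <- p[keep]
  p$track_id <- as.character(p$track_id)
  p$marker <- as.character(p$marker)
  for (cc in intersect(c(.TRACK_META_COLS, .TRACK_LABEL_COLS), names(p)))
    p[[cc]] <- as.character(p[[cc]])
  for (cc in c("time_min", "x_um", "y_um", "z_um", "intensity"))
    p[[cc]] <- as.numeric(p[[cc]])
  p$frame <- as.integer(p$frame)

  if (anyDuplicated(paste(p$track_id, p$frame, sep = "\r")))
    stop("duplicated (track_id, frame) pair in track table", call. = FALSE)

  p <- p[order(p$track_id, p$frame), , drop = FALSE]
  npts <- table(p$track_id)
  short <- names(npts)[npts < 2L]
  if (length(short)) {
    warning(sprintf("dropping %d single-point track(s): %s", length(short),
                    paste(utils::head(short, 5L), collapse = ", ")),
            call. = FALSE)
    p <- p[!(p$track_id %in% short), , drop = FALSE]
  }
  rownames(p) <- NULL

  same <- nrow(p) > 1L & p$track_id[-1L] == p$track_id[-nrow(p)]
  if (nrow(p) > 1L && any(same & diff(p$time_min) <= 0))
    stop("time_min is not strictly increasing within a track", call. = FALSE)

  new("TrackSet", points = p, frameIntervalMin = as.numeric(frameIntervalMin))
}

#' Read a spot-tracking track table
#'
#' Reads a comma-separated per-point track table (one row per track-point,
#' UTF-8, header required, decimal point) of the shape exported by
#' spot-tracking software, and returns a validated \linkS4class{TrackSet}.
#' Tracks with a single point are dropped with a warning; duplicated
#' (track_id, frame) rows or non-monotone time within a track are integrity
#' errors.
#'
#' @param path path to the CSV file.
#' @param frameIntervalMin movie sampling step in minutes.
#' @return A \linkS4class{TrackSet}.
#' @seealso \code{\link{writeTracks}} emits the same dialect.
#' @export
readTracks <- function(path, frameIntervalMin) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, encoding = "UTF-8")
  TrackSet(tab, frameIntervalMin = frameIntervalMin)
}

#' Write a TrackSet as a CSV track table
#'
#' Emits the same dialect \code{\link{readTracks}} accepts; lossless for all
#' fields up to floating-point formatting (15 significant digits). An empty
#' TrackSet yields a header-only file.
#'
#' @param x a \linkS4class{TrackSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTracks <- function(x, path) {
  stopifnot(is(x, "TrackSet"))
  utils::write.csv(x@points, file = path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter tracks by minimum duration
#'
#' Retains exactly the tracks whose wall-clock duration (last minus first
#' \code{time_min}) is at least \code{minDurationMin}; the boundary is
#' inclusive, so a track lasting exactly the threshold survives. The default
#' of 5 minutes is the standard curation step for spot-tracked lymphocyte
#' movies. Track order is preserved and the operation is idempotent.
#'
#' @param x a \linkS4class{TrackSet}.
#' @param minDurationMin non-negative threshold in minutes (default 5).
#' @return A \linkS4class{TrackSet} with the surviving tracks.
#' @export
filterMinDuration <- function(x, minDurationMin = 5) {
  stopifnot(is(x, "TrackSet"))
  if (length(minDurationMin) != 1L || !is.finite(minDurationMin) ||
      minDurationMin < 0)
    stop("minDurationMin must be a single non-negative number", call. = FALSE)
  dur <- trackDurations(x)
  keep <- names(dur)[dur >= minDurationMin]
  p <- x@points[x@points$track_id %in% keep, , drop = FALSE]
  rownames(p) <- NULL
  new("TrackSet", points = p, frameIntervalMin = x@frameIntervalMin)
}

#' Subset a TrackSet by track id
#'
#' @param x a \linkS4class{TrackSet}.
#' @param ids character vector of track ids to keep.
#' @return A \linkS4class{TrackSet}.
#' @export
subsetTracks <- function(x, ids) {
  stopifnot(is(x, "TrackSet"))
  unknown <- setdiff(ids, unique(x@points$track_id))
  if (length(unknown))
    stop("unknown track id(s): ", paste(utils::head(unknown, 5L),
                                        collapse = ", "), call. = FALSE)
  p <- x@points[x@points$track_id %in% ids, , drop = FALSE]
  rownames(p) <- NULL
  new("TrackSet", points = p, frameIntervalMin = x@frameIntervalMin)
}

#' @rdname accessors
#' @export
setMethod("trackPoints", "TrackSet", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("trackIds", "TrackSet", function(x) unique(x@points$track_id))

#' @rdname accessors
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@points$track_id)))

#' @rdname accessors
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@frameIntervalMin)

#' @describeIn accessors wall-clock duration (minutes) per track, named by
#'   track id, in TrackSet order.
#' @export
setMethod("trackDurations", "TrackSet", function(x) {
  p <- x@points
  if (!nrow(p)) return(stats::setNames(numeric(0), character(0)))
  f <- factor(p$track_id, levels = unique(p$track_id))
  dur <- tapply(p$time_min, f, function(t) t[length(t)] - t[1L])
  stats::setNames(as.numeric(dur), levels(f))
})

#' @describeIn accessors one row of metadata per track (track_id, marker,
#'   case_id, movie_id, diagnosis, plus label columns if present).
#' @export
setMethod("trackInfo", "TrackSet", function(x) {
  p <- x@points
  cols <- intersect(c("track_id", "marker", .TRACK_META_COLS,
                      .TRACK_LABEL_COLS), names(p))
  info <- p[!duplicated(p$track_id), cols, drop = FALSE]
  rownames(info) <- NULL
  info
})

setMethod("show", "TrackSet", function(object) {
  p <- object@points
  nt <- length(unique(p$track_id))
  cat(sprintf("TrackSet: %d track(s), %d point(s), frame interval %g min\n",
              nt, nrow(p), object@frameIntervalMin))
  if (nt) {
    cat("  markers: ", paste(sort(unique(p$marker)), collapse = ", "), "\n",
        sep = "")
    cat("  movies:  ", length(unique(paste(p$case_id, p$movie_id))),
        " | diagnoses: ", paste(sort(unique(p$diagnosis)), collapse = ", "),
        "\n", sep = "")
    if ("tracktype" %in% names(p)) cat("  labels:  present\n")
  }
  invisible(NULL)
})
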