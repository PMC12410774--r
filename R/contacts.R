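#' Extract maximal contact events from a temporal cell graph
#'
#' A contact event is a maximal run of consecutive frames during which a
#' pair of cells stays within the contact radius. Any frame without an edge
#' — including frames where either track is unobserved — splits a run, so
#' a pair that separates and re-meets produces distinct events. Events are
#' sorted by (movie, pair, start_frame).
#'
#' @param graph a \linkS4class{TemporalCellGraph}.
#' @return data.frame (movie_id, track_a, track_b, start_frame, end_frame,
#'   duration_frames), with \code{duration_frames = end_frame - start_frame
#'   + 1}.
#' @export
contactEvents <- function(graph) {
  stopifnot(is(graph, "TemporalCellGraph"))
  e <- graph@edges
  empty <- data.frame(movie_id = character(0), track_a = character(0),
                      track_b = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_frames = integer(0))
  if (!nrow(e)) return(empty)
  key <- paste(e$movie_id, e$track_a, e$track_b, sep = "\r")
  byPair <- split(e$frame, key)
  meta <- e[!duplicated(key), c("movie_id", "track_a", "track_b")]
  rownames(meta) <- NULL
  ord <- order(names(byPair))
  evs <- lapply(ord, function(k) {
    fr <- sort(byPair[[k]])
    runStart <- c(TRUE, diff(fr) > 1L)
    runId <- cumsum(runStart)
    start <- fr[runStart]
    end <- as.integer(tapply(fr, runId, max))
    m <- meta[match(names(byPair)[k], key[!duplicated(key)]), ]
    data.frame(movie_id = m$movie_id, track_a = m$track_a,
               track_b = m$track_b, start_frame = as.integer(start),
               end_frame = end,
               duration_frames = end - as.integer(start) + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(evs, list(empty)))
  out <- out[order(out$movie_id, out$track_a, out$track_b, out$start_frame), ]
  rownames(out) <- NULL
  out
}

#' Per-track contact statistics
#'
#' For every track of a TrackSet, counts the contact events it participates
#' in and their mean duration in frames. A shared event counts once for each
#' of its two tracks; tracks with no events get (0, 0). By convention the
#' contact count is the number of events, so a pair that separates and
#' re-meets counts twice; set \code{countBy = "partners"} to count distinct
#' contact partners instead (mean duration then still averages over events).
#'
#' @param events data.frame from \code{\link{contactEvents}}.
#' @param x the \linkS4class{TrackSet} the events were derived from.
#' @param countBy "events" (default) or "partners".
#' @return data.frame (track_id, n_contacts, mean_contact_duration_frames),
#'   one row per track in TrackSet order.
#' @export
contactStats <- function(events, x, countBy = c("events", "partners")) {
  stopifnot(is(x, "TrackSet"), is.data.frame(events))
  countBy <- match.arg(countBy)
  ids <- trackIds(x)
  long <- data.frame(
    track_id = c(events$track_a, events$track_b),
    partner = c(events$track_b, events$track_a),
    duration = c(events$duration_frames, events$duration_frames),
    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(long$track_id), ids)
  if (length(unknown))
    stop("contact event references unknown track(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  f <- factor(long$track_id, levels = ids)
  n <- if (countBy == "events") {
    as.integer(tapply(long$duration, f, length))
  } else {
    as.integer(tapply(long$partner, f, function(v) length(unique(v))))
  }
  meanDur <- as.numeric(tapply(long$duration, f, mean))
  n[is.na(n)] <- 0L
  meanDur[is.na(meanDur)] <- 0
  data.frame(track_id = ids, n_contacts = n,
             mean_contact_duration_frames = meanDur,
             stringsAsFactors = FALSE)
}

#' Write contact events as CSV
#'
#' @param events data.frame from \code{\link{contactEvents}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContactEvents <- function(events, path) {
  utils::write.csv(events, file = path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
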