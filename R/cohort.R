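#' Summarize behavior-type distributions per diagnosis group
#'
#' Computes, for every (diagnosis, marker) group and each classification
#' task, the class proportions (each track weighted equally), the track
#' count, and group motility summaries (mean and median speed, mean contact
#' count, mean contact duration). All three classes of a task are always
#' reported, with proportion 0 when absent, so tables stay rectangular;
#' a diagnosis declared in the metadata but with no tracks is reported with
#' NA proportions.
#'
#' @param labels data.frame (track_id, track_type, action_type) — ground
#'   truth or predictions.
#' @param features feature table from \code{\link{assembleFeatures}} (must
#'   carry track metadata).
#' @param metadata optional movie metadata (case_id, movie_id, diagnosis);
#'   when given, every track's movie must resolve to exactly one row, and
#'   the metadata's diagnosis overrides the one carried in \code{features}.
#' @return A \linkS4class{CohortSummary}.
#' @export
summarizeCohort <- function(labels, features, metadata = NULL) {
  labels <- .normalizeLabels(labels)
  stopifnot(all(c("track_id", "track_type", "action_type") %in% names(labels)),
            is.data.frame(features))
  m <- match(features$track_id, labels$track_id)
  if (any(is.na(m)))
    stop("unlabeled track(s): ",
         paste(utils::head(features$track_id[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  td <- data.frame(
    track_id = features$track_id,
    marker = features$marker,
    case_id = features$case_id,
    movie_id = features$movie_id,
    diagnosis = if ("diagnosis" %in% names(features)) features$diagnosis
                else NA_character_,
    track_type = labels$track_type[m],
    action_type = labels$action_type[m],
    speed_mean_um_per_min = features$speed_mean_um_per_min,
    n_contacts = features$n_contacts,
    mean_contact_duration_frames = features$mean_contact_duration_frames,
    stringsAsFactors = FALSE)
  extraGroups <- NULL
  if (!is.null(metadata)) {
    stopifnot(all(c("case_id", "movie_id", "diagnosis") %in% names(metadata)))
    key <- paste(td$case_id, td$movie_id, sep = "\r")
    mkey <- paste(metadata$case_id, metadata$movie_id, sep = "\r")
    if (anyDuplicated(mkey))
      stop("metadata has duplicated (case_id, movie_id) rows", call. = FALSE)
    mm <- match(key, mkey)
    if (any(is.na(mm)))
      stop("track(s) with no metadata row: ",
           paste(utils::head(td$track_id[is.na(mm)], 5L), collapse = ", "),
           call. = FALSE)
    td$diagnosis <- metadata$diagnosis[mm]
    extraGroups <- setdiff(unique(metadata$diagnosis), unique(td$diagnosis))
  }

  tasks <- c(track_type = "track_type", action_type = "action_type")
  grp <- interaction(td$diagnosis, td$marker, drop = TRUE, sep = "\r")
  rows <- list()
  for (g in levels(grp)) {
    sub <- td[grp == g, , drop = FALSE]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    for (task in tasks) {
      cls <- .taskClasses(task)
      prop <- as.numeric(table(factor(sub[[task]], cls))) / nrow(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        diagnosis = parts[1L], marker = parts[2L], task = task,
        class = cls, proportion = prop, n_tracks = nrow(sub),
        mean_speed_um_per_min = mean(sub$speed_mean_um_per_min),
        median_speed_um_per_min = stats::median(sub$speed_mean_um_per_min),
        mean_n_contacts = mean(sub$n_contacts),
        mean_contact_duration_frames =
          mean(sub$mean_contact_duration_frames),
        stringsAsFactors = FALSE)
    }
  }
  for (g in extraGroups) for (task in tasks)
    rows[[length(rows) + 1L]] <- data.frame(
      diagnosis = g, marker = NA_character_, task = task,
      class = NA_character_, proportion = NA_real_, n_tracks = 0L,
      mean_speed_um_per_min = NA_real_, median_speed_um_per_min = NA_real_,
      mean_n_contacts = NA_real_, mean_contact_duration_frames = NA_real_,
      stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("CohortSummary", table = tab, trackData = td)
}

#' @rdname accessors
#' @export
setMethod("summaryTable", "CohortSummary", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("trackData", "CohortSummary", function(x) x@trackData)

setMethod("show", "CohortSummary", function(object) {
  td <- object@trackData
  cat(sprintf("CohortSummary: %d track(s), %d diagnosis group(s), %d marker(s)\n",
              nrow(td), length(unique(td$diagnosis)),
              length(unique(td$marker))))
  invisible(NULL)
})

.groupStats <- function(sub) {
  c(stats::setNames(
      as.numeric(table(factor(sub$track_type, .TRACK_TYPES))) / nrow(sub),
      paste0("prop_", .TRACK_TYPES)),
    stats::setNames(
      as.numeric(table(factor(sub$action_type, .ACTION_TYPES))) / nrow(sub),
      paste0("prop_", .ACTION_TYPES)),
    mean_speed_um_per_min = mean(sub$speed_mean_um_per_min),
    mean_n_contacts = mean(sub$n_contacts),
    mean_contact_duration_frames = mean(sub$mean_contact_duration_frames))
}

#' Compare two diagnosis groups
#'
#' Differences (group A minus group B) in class proportions, mean speed,
#' mean contact count and mean contact duration, with seeded bootstrap
#' percentile intervals obtained by resampling tracks within each group.
#' The intervals are a repository addition for uncertainty quantification;
#' percentage-distribution comparisons of this kind are traditionally
#' reported without inferential statistics.
#'
#' @param summary a \linkS4class{CohortSummary}.
#' @param groupA,groupB diagnosis names present in the summary.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return data.frame (quantity, estimate, ci_lo, ci_hi).
#' @export
compareGroups <- function(summary, groupA, groupB, nBoot = 1000L,
                          seed = 1L) {
  stopifnot(is(summary, "CohortSummary"))
  td <- summary@trackData
  for (g in c(groupA, groupB))
    if (!g %in% td$diagnosis)
      stop("unknown group: ", g, call. = FALSE)
  a <- td[td$diagnosis == groupA, , drop = FALSE]
  b <- td[td$diagnosis == groupB, , drop = FALSE]
  est <- .groupStats(a) - .groupStats(b)
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(nBoot), function(i) {
    ra <- a[sample.int(nrow(a), replace = TRUE), , drop = FALSE]
    rb <- b[sample.int(nrow(b), replace = TRUE), , drop = FALSE]
    .groupStats(ra) - .groupStats(rb)
  }, numeric(length(est)))
  ci <- apply(matrix(boots, nrow = length(est)), 1L, stats::quantile,
              probs = c(0.025, 0.975))
  data.frame(quantity = names(est), estimate = unname(est),
             ci_lo = ci[1L, ], ci_hi = ci[2L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}
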