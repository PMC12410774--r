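#' Run the full track-analysis pipeline
#'
#' Executes the whole analysis in order: duration filter, motility
#' features, temporal cell graph, contact events and per-track contact
#' statistics, behavior classification, and cohort summary. The classifier
#' is either a supplied trained model, or is trained on the spot from
#' \code{trainLabels} (or from label columns carried in the tracks). The
#' pipeline is a pure function of (input, configuration, seed): rerunning
#' with the same arguments reproduces identical outputs.
#'
#' @param tracks a \linkS4class{TrackSet}, or a path (or vector of paths)
#'   to CSV track tables readable by \code{\link{readTracks}}.
#' @param metadata optional movie metadata data.frame (case_id, movie_id,
#'   diagnosis) or CSV path.
#' @param model optional trained \linkS4class{BehaviorModel}; when NULL a
#'   model is trained on the input's labels.
#' @param trainLabels optional label table used to train when \code{model}
#'   is NULL.
#' @param minDurationMin duration filter threshold in minutes (default 5).
#' @param radiusUm contact radius in micrometers (default 7).
#' @param frameIntervalMin sampling step, required when \code{tracks} is a
#'   file path.
#' @param seed integer seed for classifier training.
#' @param outDir optional directory; when given, the feature table,
#'   predictions, contact events, graph edge list and summary are written
#'   there as CSV.
#' @return list(features, predictions, summary, events, manifest); with an
#'   empty input, \code{summary} is an empty \linkS4class{CohortSummary}
#'   and a warning is emitted.
#' @export
runPipeline <- function(tracks, metadata = NULL, model = NULL,
                        trainLabels = NULL, minDurationMin = 5,
                        radiusUm = 7, frameIntervalMin = NULL, seed = 1L,
                        outDir = NULL) {
  if (is.character(tracks)) {
    if (is.null(frameIntervalMin))
      stop("frameIntervalMin is required when reading tracks from file",
           call. = FALSE)
    pts <- do.call(rbind, lapply(tracks, function(f)
      trackPoints(readTracks(f, frameIntervalMin))))
    tracks <- TrackSet(pts, frameIntervalMin = frameIntervalMin)
  }
  stopifnot(is(tracks, "TrackSet"))
  if (is.character(metadata)) metadata <- utils::read.csv(metadata,
    stringsAsFactors = FALSE)

  manifest <- list(
    minDurationMin = minDurationMin, radiusUm = radiusUm,
    seed = as.integer(seed),
    frameIntervalMin = frameInterval(tracks),
    nTracksIn = nTracks(tracks),
    package = "LymphoDyn4D",
    version = as.character(utils::packageVersion("LymphoDyn4D")))

  kept <- filterMinDuration(tracks, minDurationMin)
  if (nTracks(kept) == 0L) {
    warning("no tracks survive the duration filter; returning empty results",
            call. = FALSE)
    emptySummary <- new("CohortSummary",
                        table = data.frame(), trackData = data.frame())
    return(list(features = motilityFeatures(kept),
                predictions = data.frame(track_id = character(0),
                                         track_type = character(0),
                                         action_type = character(0)),
                summary = emptySummary,
                events = contactEvents(buildTemporalGraph(kept, radiusUm)),
                manifest = manifest))
  }

  graph <- buildTemporalGraph(kept, radiusUm = radiusUm)
  events <- contactEvents(graph)
  stats <- contactStats(events, kept)
  features <- assembleFeatures(kept, stats)

  if (is.null(model))
    model <- trainBehaviorModel(features, labels = trainLabels, seed = seed)
  predictions <- predictBehavior(model, features)
  summary <- summarizeCohort(predictions, features, metadata = metadata)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(features, file.path(outDir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    writeContactEvents(events, file.path(outDir, "contact_events.csv"))
    exportTemporalGraph(graph, file.path(outDir, "graph_edges.csv"))
    utils::write.csv(summaryTable(summary), file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  list(features = features, predictions = predictions, summary = summary,
       events = events, manifest = manifest)
}
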