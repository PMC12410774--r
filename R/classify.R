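## Behavior classification: the 7-feature table, repeated stratified CV and
## the paired random-forest model for track types (LM/MT/LD) and action
## types (PC/IC/AC).

.FEATURE_NAMES <- c("displacement_length_um", "track_length_um",
                    "speed_mean_um_per_min", "straightness",
                    "intensity_mean", "n_contacts",
                    "mean_contact_duration_frames")

.normalizeLabels <- function(labels) {
  nm <- names(labels)
  nm[nm == "tracktype"] <- "track_type"
  nm[nm == "actiontype"] <- "action_type"
  names(labels) <- nm
  labels
}

.taskColumn <- function(task) {
  switch(task, track_type = "track_type", action_type = "action_type",
         stop("task must be 'track_type' or 'action_type'", call. = FALSE))
}

.taskClasses <- function(task)
  if (task == "track_type") .TRACK_TYPES else .ACTION_TYPES

#' Assemble the 7-feature classification table
#'
#' Joins the five per-track motility features with the two contact features
#' (event count and mean contact duration in frames) into the feature table
#' used for behavior classification, keeping track metadata and any label
#' columns. The feature column order is fixed and recorded in trained
#' models.
#'
#' @param x a \linkS4class{TrackSet}.
#' @param stats per-track contact statistics from \code{\link{contactStats}}.
#' @return data.frame, one row per track: metadata (+ labels if present)
#'   followed by the 7 feature columns in canonical order.
#' @export
assembleFeatures <- function(x, stats) {
  stopifnot(is(x, "TrackSet"), is.data.frame(stats))
  feat <- motilityFeatures(x)
  miss <- setdiff(feat$track_id, stats$track_id)
  if (length(miss))
    stop("track(s) missing contact stats: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  m <- match(feat$track_id, stats$track_id)
  feat$n_contacts <- stats$n_contacts[m]
  feat$mean_contact_duration_frames <- stats$mean_contact_duration_frames[m]
  meta <- setdiff(names(feat), .FEATURE_NAMES)
  feat[c(meta, .FEATURE_NAMES)]
}

.featureMatrix <- function(features) {
  miss <- setdiff(.FEATURE_NAMES, names(features))
  if (length(miss))
    stop("feature table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- features[.FEATURE_NAMES]
  if (any(!vapply(m, is.numeric, TRUE)) || any(is.na(as.matrix(m))) ||
      any(!is.finite(as.matrix(m))))
    stop("features must be finite numeric (no NA/NaN)", call. = FALSE)
  as.data.frame(m)
}

.taskLabels <- function(features, labels, task) {
  col <- .taskColumn(task)
  if (is.null(labels)) {
    labels <- .normalizeLabels(features)
    if (!col %in% names(labels))
      stop("no '", col, "' labels found in the feature table; ",
           "pass a label table", call. = FALSE)
    y <- labels[[col]]
  } else {
    labels <- .normalizeLabels(labels)
    if (!all(c("track_id", col) %in% names(labels)))
      stop("label table needs columns track_id and ", col, call. = FALSE)
    m <- match(features$track_id, labels$track_id)
    if (any(is.na(m)))
      stop("label table is missing track(s): ",
           paste(utils::head(features$track_id[is.na(m)], 5L),
                 collapse = ", "), call. = FALSE)
    y <- labels[[col]][m]
  }
  bad <- setdiff(unique(y), .taskClasses(task))
  if (length(bad))
    stop("unknown ", col, " label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  factor(y, levels = intersect(.taskClasses(task), unique(y)))
}

.stratifiedFolds <- function(y, nFolds) {
  ## fold id per sample; every class spread as evenly as possible
  tooFew <- names(which(table(y) < nFolds))
  if (length(tooFew))
    stop("class(es) with fewer samples than folds: ",
         paste(tooFew, collapse = ", "), call. = FALSE)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

.fitForest <- function(xmat, y, ntree, mtry) {
  randomForest::randomForest(x = xmat, y = y, ntree = ntree, mtry = mtry)
}

.predictClasses <- function(forest, xmat, classes) {
  prob <- stats::predict(forest, newdata = xmat, type = "prob")
  prob <- prob[, classes[classes %in% colnames(prob)], drop = FALSE]
  factor(colnames(prob)[max.col(prob, ties.method = "first")],
         levels = colnames(prob))
}

#' Repeated stratified cross-validation of a behavior task
#'
#' Evaluates a random-forest classifier on one task (track types or action
#' types) by stratified k-fold cross-validation repeated \code{nRepeats}
#' times with distinct fold shuffles. Reports one pooled hold-out accuracy
#' per repeat, the confusion matrix pooled over all repeats and folds, and
#' per-class precision/recall. Fully deterministic for a fixed seed.
#'
#' @param features feature table from \code{\link{assembleFeatures}}.
#' @param labels optional label table (track_id, track_type, action_type);
#'   if NULL, label columns carried in \code{features} are used.
#' @param task "track_type" or "action_type".
#' @param nRepeats number of CV repetitions (default 20).
#' @param nFolds folds per repetition (default 5).
#' @param seed integer RNG seed.
#' @param ntree,mtry forest hyperparameters (defaults 100 trees,
#'   sqrt-features per split).
#' @return A \linkS4class{ValidationReport}.
#' @export
crossValidate <- function(features, labels = NULL,
                          task = c("track_type", "action_type"),
                          nRepeats = 20L, nFolds = 5L, seed = 1L,
                          ntree = 100L, mtry = NULL) {
  task <- match.arg(task)
  xmat <- .featureMatrix(features)
  y <- .taskLabels(features, labels, task)
  if (nlevels(y) < 2L)
    stop("need at least 2 classes for cross-validation", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(xmat))))
  nRepeats <- as.integer(nRepeats); nFolds <- as.integer(nFolds)
  seed <- as.integer(seed)

  set.seed(seed)
  classes <- levels(y)
  confusion <- matrix(0L, nlevels(y), nlevels(y),
                      dimnames = list(true = classes, predicted = classes))
  accuracies <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    fold <- .stratifiedFolds(y, nFolds)
    hit <- 0L
    for (k in seq_len(nFolds)) {
      test <- fold == k
      fit <- .fitForest(xmat[!test, , drop = FALSE], droplevels(y[!test]),
                        ntree, mtry)
      pred <- .predictClasses(fit, xmat[test, , drop = FALSE], classes)
      hit <- hit + sum(as.character(pred) == as.character(y[test]))
      confusion <- confusion + unclass(table(factor(y[test], classes),
                                             factor(pred, classes)))
    }
    accuracies[r] <- hit / length(y)
  }
  support <- rowSums(confusion)
  perClass <- data.frame(
    class = classes,
    precision = ifelse(colSums(confusion) > 0,
                       diag(confusion) / colSums(confusion), NA_real_),
    recall = ifelse(support > 0, diag(confusion) / support, NA_real_),
    support = as.integer(support), row.names = NULL)
  new("ValidationReport", task = task, accuracies = accuracies,
      confusion = confusion, perClass = perClass,
      nRepeats = nRepeats, nFolds = nFolds, seed = seed)
}

#' @rdname accessors
#' @export
setMethod("meanAccuracy", "ValidationReport",
          function(x) mean(x@accuracies))

#' @rdname accessors
#' @export
setMethod("sdAccuracy", "ValidationReport",
          function(x) stats::sd(x@accuracies))

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "ValidationReport", function(x) x@confusion)

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf(
    "ValidationReport [%s]: accuracy %.4f +/- %.4f (%dx stratified %d-fold CV, seed %d)\n",
    object@task, mean(object@accuracies), stats::sd(object@accuracies),
    object@nRepeats, object@nFolds, object@seed))
  invisible(NULL)
})

#' Train the paired behavior classifier
#'
#' Fits two independent random forests on the 7-feature table: one for
#' track types and one for action types. The feature schema, seed and
#' hyperparameters are stored in the model so prediction is reproducible;
#' the model can be persisted with \code{saveRDS} and reloaded with
#' \code{readRDS}.
#'
#' @inheritParams crossValidate
#' @return A \linkS4class{BehaviorModel}.
#' @export
trainBehaviorModel <- function(features, labels = NULL, seed = 1L,
                               ntree = 100L, mtry = NULL) {
  xmat <- .featureMatrix(features)
  yTrack <- .taskLabels(features, labels, "track_type")
  yAction <- .taskLabels(features, labels, "action_type")
  if (nlevels(yTrack) < 2L || nlevels(yAction) < 2L)
    stop("need at least 2 classes per task for training", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(xmat))))
  seed <- as.integer(seed)
  set.seed(seed)
  trackForest <- .fitForest(xmat, yTrack, ntree, mtry)
  actionForest <- .fitForest(xmat, yAction, ntree, mtry)
  new("BehaviorModel", trackForest = trackForest,
      actionForest = actionForest, featureNames = .FEATURE_NAMES,
      seed = seed, trackClasses = levels(yTrack),
      actionClasses = levels(yAction),
      hyperparameters = list(ntree = as.integer(ntree),
                             mtry = as.integer(mtry)))
}

setMethod("show", "BehaviorModel", function(object) {
  cat(sprintf(
    "BehaviorModel: %d features, %d trees, seed %d\n  track types:  %s\n  action types: %s\n",
    length(object@featureNames), object@hyperparameters$ntree, object@seed,
    paste(object@trackClasses, collapse = "/"),
    paste(object@actionClasses, collapse = "/")))
  invisible(NULL)
})

#' Predict track and action types
#'
#' Applies a trained \linkS4class{BehaviorModel} to a feature table. The
#' table must contain the model's feature schema (extra columns ignored,
#' order-insensitive); NA features are an input error. Each task assigns
#' the class with maximal predicted probability, ties broken by the fixed
#' class orders LM < MT < LD and PC < IC < AC.
#'
#' @param model a \linkS4class{BehaviorModel}.
#' @param features feature table from \code{\link{assembleFeatures}}.
#' @return data.frame (track_id, track_type, action_type).
#' @export
predictBehavior <- function(model, features) {
  stopifnot(is(model, "BehaviorModel"))
  miss <- setdiff(model@featureNames, names(features))
  if (length(miss))
    stop("feature table does not match the model schema; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  xmat <- .featureMatrix(features)[model@featureNames]
  data.frame(
    track_id = features$track_id,
    track_type = as.character(
      .predictClasses(model@trackForest, xmat, model@trackClasses)),
    action_type = as.character(
      .predictClasses(model@actionForest, xmat, model@actionClasses)),
    stringsAsFactors = FALSE)
}

#' Compare predicted labels against a reference annotation
#'
#' Label-comparison report for manual validation of the classifier:
#' per-task agreement (accuracy) and confusion matrices between a
#' prediction table and a reference (e.g. human-annotated) label table,
#' matched by track id.
#'
#' @param predicted data.frame (track_id, track_type, action_type).
#' @param reference data.frame with the same columns (or
#'   tracktype/actiontype).
#' @return list with \code{track_type} and \code{action_type} elements,
#'   each holding \code{accuracy}, \code{n} and \code{confusion}.
#' @export
compareLabels <- function(predicted, reference) {
  predicted <- .normalizeLabels(predicted)
  reference <- .normalizeLabels(reference)
  m <- match(predicted$track_id, reference$track_id)
  if (any(is.na(m)))
    stop("reference is missing track(s): ",
         paste(utils::head(predicted$track_id[is.na(m)], 5L),
               collapse = ", "), call. = FALSE)
  out <- lapply(c(track_type = "track_type", action_type = "action_type"),
    function(col) {
      pred <- predicted[[col]]
      ref <- reference[[col]][m]
      cls <- .taskClasses(col)
      list(accuracy = mean(pred == ref), n = length(pred),
           confusion = table(true = factor(ref, cls),
                             predicted = factor(pred, cls)))
    })
  out
}
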