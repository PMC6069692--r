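# Cost-sensitive four-way relation classification
# ({OVERLAP, BEFORE, AFTER, NO_RELATION}) and the deterministic
# post-processing filters. The classifier is an SVM (LibSVM via e1071) with
# per-class weights inversely proportional to class frequency.

#' Inverse-frequency class weights
#'
#' Computes `w(t) = N / (K * count(t))` with `K` the number of labels, so a
#' perfectly balanced training set gets unit weights and
#' `sum(count * weight) = N` always holds. Weights are passed to the SVM as
#' per-class misclassification costs.
#'
#' @param label_counts Named vector of per-label training counts (all > 0).
#' @return Named numeric weight vector.
#' @export
compute_class_weights <- function(label_counts) {
  counts <- as.numeric(label_counts)
  if (any(counts <= 0) || anyNA(counts)) {
    stop("all label counts must be positive (degenerate training set)",
         call. = FALSE)
  }
  w <- sum(counts) / (length(counts) * counts)
  names(w) <- names(label_counts)
  w
}

#' Training configuration
#'
#' @param cost SVM regularization constant C.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param gamma RBF kernel width (ignored for the linear kernel).
#' @param cost_sensitive Apply inverse-frequency class weights.
#' @param tune Select `cost` by cross-validation over `tune_grid` before the
#'   final fit.
#' @param tune_grid,tune_folds Candidate costs and fold count for tuning.
#' @param seed Seed fixing fold assignment (and any other randomness).
#' @param negative_ratio Optional subsampling ratio for NO_RELATION
#'   instances (`NULL` keeps all negatives).
#' @param use_decision_features Include the rule engine's verdict as
#'   features when building instances.
#' @return A list of class `train_config`.
#' @export
train_config <- function(cost = 1, kernel = c("linear", "radial"),
                         gamma = NULL, cost_sensitive = TRUE, tune = FALSE,
                         tune_grid = c(0.1, 1, 10), tune_folds = 5,
                         seed = 1L, negative_ratio = NULL,
                         use_decision_features = TRUE) {
  structure(list(cost = cost, kernel = match.arg(kernel), gamma = gamma,
                 cost_sensitive = isTRUE(cost_sensitive),
                 tune = isTRUE(tune), tune_grid = tune_grid,
                 tune_folds = tune_folds, seed = as.integer(seed),
                 negative_ratio = negative_ratio,
                 use_decision_features = isTRUE(use_decision_features)),
            class = "train_config")
}

#' Train the relation classifier
#'
#' @param features List of sparse feature vectors ([extract_features()]).
#' @param labels Character vector of labels over
#'   `OVERLAP`/`BEFORE`/`AFTER`/`NO_RELATION`, aligned with `features`.
#' @param config A [train_config()].
#' @return A model of class `dtr_model`; prediction is a pure function of
#'   (model, features).
#' @export
train_classifier <- function(features, labels, config = train_config()) {
  stopifnot(length(features) == length(labels))
  levels <- intersect(CLASS_LABELS, unique(labels))
  if (length(levels) < 2) {
    stop("training requires at least two distinct labels", call. = FALSE)
  }
  y <- factor(labels, levels = levels)
  x <- build_feature_matrix(features)
  weights <- if (config$cost_sensitive) {
    compute_class_weights(table(y))
  } else {
    stats::setNames(rep(1, length(levels)), levels)
  }
  cost <- config$cost
  if (config$tune) {
    cost <- tune_cost(x, y, weights, config)
  }
  set.seed(config$seed)
  fit <- e1071::svm(x = x, y = y, kernel = config$kernel, cost = cost,
                    gamma = if (is.null(config$gamma)) 1 / ncol(x) else
                      config$gamma,
                    class.weights = weights, scale = FALSE,
                    probability = FALSE)
  structure(list(svm = fit, feature_names = colnames(x), levels = levels,
                 class_weights = weights, cost = cost, config = config),
            class = "dtr_model")
}

tune_cost <- function(x, y, weights, config) {
  set.seed(config$seed)
  folds <- sample(rep_len(seq_len(config$tune_folds), length(y)))
  acc <- vapply(config$tune_grid, function(cc) {
    correct <- 0L
    for (k in seq_len(config$tune_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2) next
      fit <- e1071::svm(x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
                        kernel = config$kernel, cost = cc,
                        class.weights = weights[levels(droplevels(y[tr]))],
                        scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    correct
  }, numeric(1))
  config$tune_grid[which.max(acc)]
}

#' Predict labels for feature vectors
#'
#' Features unseen at training time are ignored.
#'
#' @param model A `dtr_model`.
#' @param features List of sparse feature vectors.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, features) {
  if (!length(features)) return(character(0))
  x <- build_feature_matrix(features, model$feature_names)
  as.character(stats::predict(model$svm, x))
}

#' Save / load a trained model
#'
#' Models serialize losslessly through R's native serialization; the file
#' embeds the package's model-format version.
#'
#' @param model A `dtr_model`.
#' @param path File path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_model <- function(model, path) {
  saveRDS(list(format = "dirtlink-model-1", model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dirtlink-model-1")) {
    stop("not a dirtlink model file: ", path, call. = FALSE)
  }
  obj$model
}

#' Post-process predicted relations
#'
#' Applies the two deterministic false-positive filters: a predicted relation
#' is removed (set to `NO_RELATION`) when (a) the event is of type PROBLEM,
#' the time expression of type FREQUENCY, and the time's surface form is a
#' medication dosing frequency (e.g. "bid", "prn", "q2h"), or (b) the token
#' "where" occurs strictly between the two mentions. The filters only ever
#' remove predictions - never add or retype - and are idempotent.
#'
#' @param predictions Data frame with columns `time_id`, `event_id`, `label`
#'   (plus anything else, preserved).
#' @param doc The pairs' [new_document()].
#' @param med_lexicon Medication-frequency terms
#'   ([medication_frequency_lexicon()]).
#' @return `predictions` with filtered rows set to label `NO_RELATION` and a
#'   logical column `removed_by_postprocess`.
#' @export
postprocess_predictions <- function(predictions, doc,
                                    med_lexicon =
                                      medication_frequency_lexicon()) {
  if (!nrow(predictions)) {
    predictions$removed_by_postprocess <- logical(0)
    return(predictions)
  }
  m <- doc$mentions
  ti <- match(predictions$time_id, m$id)
  ei <- match(predictions$event_id, m$id)
  freq_problem <- m$event_type[ei] == "PROBLEM" &
    m$time_type[ti] == "FREQUENCY" &
    tolower(trimws(m$text[ti])) %in% med_lexicon
  where_between <- vapply(seq_len(nrow(predictions)), function(i) {
    lo <- min(m$end[ti[i]], m$end[ei[i]])
    hi <- max(m$start[ti[i]], m$start[ei[i]])
    if (lo > hi) return(FALSE)
    s <- doc$sentences[[m$sentence_index[ti[i]]]]
    tok <- s$tokens
    any(tolower(tok$text) == "where" & tok$start >= lo & tok$end <= hi)
  }, logical(1))
  hit <- (freq_problem | where_between) & predictions$label != "NO_RELATION"
  predictions$label[hit] <- "NO_RELATION"
  predictions$removed_by_postprocess <- hit
  predictions
}
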