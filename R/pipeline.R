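# End-to-end wiring: corpus-construction chain (closure -> intra-sentential
# time-event filter), instance building, corpus-level training, document
# prediction with post-processing, and a seeded synthetic experiment used by
# the test-suite and the acceptance script.

#' Corpus-construction chain for one document
#'
#' Extends the document's gold relations to their transitive closure,
#' reports contradictions, and keeps only canonically oriented
#' intra-sentential time-event relations - the candidate set reviewed for
#' directness during corpus construction.
#'
#' @param doc A [new_document()] carrying gold relations.
#' @return List with `closed`, `filtered` ([relation_graph()]s) and
#'   `contradictions` ([find_contradictions()] table).
#' @export
corpus_construction <- function(doc) {
  closed <- transitive_closure(doc$relations)
  list(closed = closed,
       filtered = filter_intra_sentential_time_event(closed, doc),
       contradictions = find_contradictions(doc$relations))
}

#' Build labelled classification instances for a document
#'
#' Enumerates candidate pairs, runs the rule engine (whose verdict becomes
#' decision-aid features unless disabled), extracts features, and assigns
#' labels from the gold direct-pair table: a candidate absent from the gold
#' direct set is a NO_RELATION instance.
#'
#' @param doc A [new_document()].
#' @param gold Gold table with columns `time_id`, `event_id`, `rel_type`
#'   (rows for direct pairs; `NULL` for unlabelled prediction-time use).
#' @inheritParams maximal_head_projection
#' @param use_decision_features Include rule-engine decision aids.
#' @return List with `meta` (pair table incl. `label` when gold given) and
#'   `features` (list of sparse vectors).
#' @export
build_instances <- function(doc, gold = NULL,
                            lexicon = type_preserving_lexicon(),
                            head_table = default_head_table(),
                            options = rule_options(),
                            use_decision_features = TRUE) {
  cand <- enumerate_candidates(doc)
  feats <- vector("list", nrow(cand))
  labels <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- doc$sentences[[cand$sentence_index[i]]]
    tm <- mention_row(doc, cand$time_id[i])
    em <- mention_row(doc, cand$event_id[i])
    dec <- if (use_decision_features) {
      classify_pair(tm, em, s, lexicon, head_table, options)
    } else {
      NULL
    }
    feats[[i]] <- extract_features(tm, em, s, decision = dec)
    if (!is.null(gold)) {
      hit <- which(gold$time_id == cand$time_id[i] &
                     gold$event_id == cand$event_id[i] &
                     !is.na(gold$rel_type))
      labels[i] <- if (length(hit)) gold$rel_type[hit[1]] else "NO_RELATION"
    }
  }
  meta <- cbind(data.frame(doc_id = rep(doc$doc_id, nrow(cand)),
                           stringsAsFactors = FALSE), cand)
  if (!is.null(gold)) meta$label <- labels
  list(meta = meta, features = feats)
}

collect_instances <- function(docs, gold, ...) {
  metas <- list()
  feats <- list()
  for (doc in docs) {
    g <- gold[gold$doc_id == doc$doc_id, , drop = FALSE]
    inst <- build_instances(doc, gold = g, ...)
    metas[[length(metas) + 1L]] <- inst$meta
    feats <- c(feats, inst$features)
  }
  list(meta = do.call(rbind, metas), features = feats)
}

#' Train the relation classifier on an annotated corpus
#'
#' @param docs List of documents.
#' @param gold Gold direct-pair table (as produced by [generate_corpus()]).
#' @param config A [train_config()].
#' @inheritParams build_instances
#' @return A `dtr_model`.
#' @export
train_corpus_model <- function(docs, gold, config = train_config(),
                               lexicon = type_preserving_lexicon(),
                               head_table = default_head_table(),
                               options = rule_options()) {
  inst <- collect_instances(docs, gold, lexicon = lexicon,
                            head_table = head_table, options = options,
                            use_decision_features =
                              config$use_decision_features)
  labels <- inst$meta$label
  feats <- inst$features
  if (!is.null(config$negative_ratio)) {
    pos <- which(labels != "NO_RELATION")
    neg <- which(labels == "NO_RELATION")
    set.seed(config$seed)
    keep_n <- min(length(neg),
                  ceiling(config$negative_ratio * length(pos)))
    keep <- sort(c(pos, sample(neg, keep_n)))
    labels <- labels[keep]
    feats <- feats[keep]
  }
  train_classifier(feats, labels, config)
}

#' Predict direct temporal relations for a document
#'
#' Runs candidate enumeration, feature extraction, the classifier, and the
#' post-processing filters; pairs labelled other than NO_RELATION become
#' canonically oriented (time as source) relations.
#'
#' @param model A trained `dtr_model`.
#' @param doc A [new_document()].
#' @param med_lexicon Medication-frequency lexicon for post-processing.
#' @inheritParams build_instances
#' @return List with `pairs` (per-candidate table incl. predicted `label`
#'   and `removed_by_postprocess`) and `graph` (the predicted
#'   [relation_graph()]).
#' @export
predict_relations <- function(model, doc,
                              med_lexicon = medication_frequency_lexicon(),
                              lexicon = type_preserving_lexicon(),
                              head_table = default_head_table(),
                              options = rule_options()) {
  inst <- build_instances(doc, gold = NULL, lexicon = lexicon,
                          head_table = head_table, options = options,
                          use_decision_features =
                            model$config$use_decision_features)
  pairs <- inst$meta
  pairs$label <- if (nrow(pairs)) {
    predict_labels(model, inst$features)
  } else {
    character(0)
  }
  pairs <- postprocess_predictions(pairs, doc, med_lexicon)
  keep <- pairs$label != "NO_RELATION"
  graph <- relation_graph(pairs$time_id[keep], pairs$event_id[keep],
                          pairs$label[keep])
  list(pairs = pairs, graph = graph)
}

#' Synthetic end-to-end experiment
#'
#' Generates a corpus, splits documents into train/held-out sets, trains the
#' cost-sensitive classifier, predicts on the held-out documents, and scores
#' both at the instance level (four-way label macro-F1) and with the
#' closure-extended relation evaluation.
#'
#' @param gen_config A [generator_config()].
#' @param config A [train_config()].
#' @param train_fraction Fraction of documents used for training.
#' @return List with the corpus, model, held-out pair table (`pairs`, with
#'   `label` and `gold_label`), `instance_macro_f1` (0-1), per-label recall
#'   vectors, and `relation_eval` (an `eval_report`).
#' @export
run_experiment <- function(gen_config = generator_config(),
                           config = train_config(),
                           train_fraction = 0.8) {
  corpus <- generate_corpus(gen_config)
  docs <- corpus$documents
  n_train <- max(1L, floor(train_fraction * length(docs)))
  train_docs <- docs[seq_len(n_train)]
  test_docs <- docs[setdiff(seq_along(docs), seq_len(n_train))]
  model <- train_corpus_model(train_docs, corpus$gold, config)

  pairs <- list()
  pred_graphs <- list()
  gold_graphs <- list()
  for (doc in test_docs) {
    res <- predict_relations(model, doc)
    g <- corpus$gold[corpus$gold$doc_id == doc$doc_id, , drop = FALSE]
    p <- res$pairs
    gl <- character(nrow(p))
    for (i in seq_len(nrow(p))) {
      hit <- which(g$time_id == p$time_id[i] & g$event_id == p$event_id[i] &
                     !is.na(g$rel_type))
      gl[i] <- if (length(hit)) g$rel_type[hit[1]] else "NO_RELATION"
    }
    p$gold_label <- gl
    pairs[[length(pairs) + 1L]] <- p
    pred_graphs[[doc$doc_id]] <- res$graph
    gold_graphs[[doc$doc_id]] <- doc$relations
  }
  pairs <- do.call(rbind, pairs)

  recall_by_label <- vapply(CLASS_LABELS, function(l) {
    n <- sum(pairs$gold_label == l)
    if (n == 0) NA_real_ else sum(pairs$gold_label == l & pairs$label == l) / n
  }, numeric(1))

  # pooled closure-extended relation evaluation over held-out documents
  tp <- fp <- fn <- 0L
  for (doc in test_docs) {
    ev <- evaluate_relations(pred_graphs[[doc$doc_id]],
                             gold_graphs[[doc$doc_id]], doc, extend = TRUE)
    tp <- tp + sum(ev$per_label$tp)
    fp <- fp + sum(ev$per_label$fp)
    fn <- fn + sum(ev$per_label$fn)
  }
  list(corpus = corpus, model = model, pairs = pairs,
       instance_macro_f1 = macro_f1(pairs$gold_label, pairs$label,
                                    intersect(CLASS_LABELS,
                                              unique(pairs$gold_label))),
       recall_by_label = recall_by_label,
       relation_micro = list(
         precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
         recall = if (tp + fn > 0) 100 * tp / (tp + fn) else 0,
         f1 = if (2 * tp + fp + fn > 0) 200 * tp / (2 * tp + fp + fn) else 0))
}
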