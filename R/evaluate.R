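# Closure-extended evaluation of predicted direct temporal relations, and
# Cohen's kappa for annotation agreement. All metrics are reported on the
# 0-100 percent scale.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Closure-extended evaluation of predicted relations
#'
#' With `extend = TRUE` (the protocol used for direct-relation scoring) both
#' relation sets are first extended to their transitive closures, then
#' restricted to canonically oriented intra-sentential time-event relations,
#' and finally compared as sets, so relations entailed by the annotations are
#' credited. A prediction is a typed true positive when the identically
#' oriented gold relation with the same type exists; detection-only metrics
#' ignore the type. When a gold pair carries contradictory types after
#' closure, all are kept, a prediction matching any of them counts, and the
#' report flags the condition.
#'
#' @param pred,gold [relation_graph()]s over the document's mentions.
#' @param doc The [new_document()].
#' @param extend Apply the closure-and-filter extension first.
#' @return An `eval_report`: per-label counts and precision/recall/F1,
#'   micro-averaged metrics, detection-only metrics, and the flag
#'   `gold_contradictions`.
#' @export
evaluate_relations <- function(pred, gold, doc, extend = TRUE) {
  check_ids <- function(g) {
    miss <- setdiff(unique(c(g$source, g$target)), doc$mentions$id)
    if (length(miss)) {
      stop("relation references unknown mention id(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  check_ids(pred)
  check_ids(gold)
  if (extend) {
    pred <- transitive_closure(pred)
    gold <- transitive_closure(gold)
  }
  pred <- filter_intra_sentential_time_event(pred, doc)
  gold <- filter_intra_sentential_time_event(gold, doc)

  pair_key <- function(g) paste(g$source, g$target, sep = "\r")
  full_key <- function(g) paste(g$source, g$target, g$type, sep = "\r")
  pk_pred <- pair_key(pred)
  pk_gold <- pair_key(gold)
  fk_pred <- full_key(pred)
  fk_gold <- full_key(gold)

  labels <- intersect(REL_TYPES, unique(c(pred$type, gold$type)))
  per <- data.frame(label = labels, tp = 0L, fp = 0L, fn = 0L,
                    precision = 0, recall = 0, f1 = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    l <- labels[i]
    p <- fk_pred[pred$type == l]
    g <- fk_gold[gold$type == l]
    per$tp[i] <- length(intersect(p, g))
    per$fp[i] <- length(setdiff(p, g))
    per$fn[i] <- length(setdiff(g, p))
    per[i, c("precision", "recall", "f1")] <-
      prf(per$tp[i], per$fp[i], per$fn[i])
  }
  micro <- prf(sum(per$tp), sum(per$fp), sum(per$fn))
  det_tp <- length(intersect(unique(pk_pred), unique(pk_gold)))
  detection <- prf(det_tp, length(unique(pk_pred)) - det_tp,
                   length(unique(pk_gold)) - det_tp)
  structure(list(per_label = per,
                 micro = as.list(micro),
                 detection = as.list(detection),
                 n_pred = nrow(pred), n_gold = nrow(gold),
                 gold_contradictions = anyDuplicated(pk_gold) > 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Relation evaluation (percent scale)\n")
  cat(sprintf("  micro:     P %.2f  R %.2f  F1 %.2f  (%d pred, %d gold)\n",
              x$micro$precision, x$micro$recall, x$micro$f1,
              x$n_pred, x$n_gold))
  cat(sprintf("  detection: P %.2f  R %.2f  F1 %.2f\n",
              x$detection$precision, x$detection$recall, x$detection$f1))
  for (i in seq_len(nrow(x$per_label))) {
    cat(sprintf("  %-8s P %.2f  R %.2f  F1 %.2f  (tp %d fp %d fn %d)\n",
                x$per_label$label[i], x$per_label$precision[i],
                x$per_label$recall[i], x$per_label$f1[i],
                x$per_label$tp[i], x$per_label$fp[i], x$per_label$fn[i]))
  }
  if (x$gold_contradictions) {
    cat("  note: gold side carries contradictory types on some pairs\n")
  }
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label sequences over the same
#' items, reported on the 0-100 scale:
#' `kappa = 100 * (p_o - p_e) / (1 - p_e)` with `p_e` from the product of
#' marginal label distributions. Perfect agreement returns 100 (also in the
#' degenerate single-label case where `p_e = 1`). The function is
#' label-agnostic: for annotation agreement on candidate pairs it can be
#' applied to the four-way labels (`direct:before`, `direct:after`,
#' `direct:overlap`, `non-direct`) or to the binary direct/non-direct
#' collapse.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa on the 0-100 scale.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  if (!length(labels_a)) {
    stop("kappa requires at least one item", call. = FALSE)
  }
  lv <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lv)
  b <- factor(labels_b, levels = lv)
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (1 - pe < .Machine$double.eps) {
    return(if (po == 1) 100 else 0)
  }
  100 * (po - pe) / (1 - pe)
}

#' Macro-averaged F1 of a label confusion
#'
#' @param truth,pred Equal-length label vectors.
#' @param levels Labels to average over (defaults to those present in
#'   `truth`).
#' @return Macro F1 on the 0-1 scale.
#' @export
macro_f1 <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(truth))
  f1s <- vapply(levels, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    unname(prf(tp, fp, fn)["f1"] / 100)
  }, numeric(1))
  mean(f1s)
}
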