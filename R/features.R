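# Feature extraction for candidate time-event pairs. Features are sparse
# named numeric vectors (binary indicators and small counts); extraction is a
# pure function of the pair and its sentence analyses, so a pair's vector
# never depends on batch composition. Families whose underlying analysis is
# missing (no tree, no frames) are simply omitted.

PUNCT_RE <- "^[[:punct:]]+$"

feat_name <- function(...) {
  x <- paste0(...)
  gsub("[[:space:]]+", "_", x)
}

verb_tense <- function(pos) {
  switch(pos,
         VBD = "past", VBN = "past",
         VBZ = "present", VBP = "present",
         MD = "future",
         "other")
}

dep_ancestors <- function(deps, tok, n_tokens) {
  out <- integer(0)
  cur <- tok
  steps <- 0L
  while (steps <= n_tokens) {
    out <- c(out, cur)
    nxt <- deps$head[match(cur, deps$dep)]
    if (is.na(nxt) || nxt == 0L || nxt %in% out) break
    cur <- nxt
    steps <- steps + 1L
  }
  out
}

#' Extract the feature vector of a candidate pair
#'
#' Emits the feature families used by the relation classifier: mention
#' attribute indicators (time type; event type/polarity/modality), bags of
#' mention tokens, three preceding/following context tokens per mention, the
#' bag and count of in-between tokens, mention POS tags, in-between
#' punctuation count, tense-and-position of sentence verbs, section label,
#' sentence-type flags, dependency features (POS of the lowest common
#' ancestor token, a noun-on-path indicator), semantic-role features (each
#' mention's predicate lemma, a same-predicate indicator), and - when a rule
#' engine decision is supplied - the decision's verdict and rationale.
#'
#' @param time,event Mention rows from the same sentence.
#' @param sentence The pair's [annotated_sentence()].
#' @param decision Optional [classify_pair()] result, included as decision-aid
#'   features (set `NULL` to ablate).
#' @return Named numeric vector (sparse; absent features are zero).
#' @export
extract_features <- function(time, event, sentence, decision = NULL) {
  tok <- sentence$tokens
  n <- nrow(tok)
  trng <- mention_token_range(time, sentence)
  erng <- mention_token_range(event, sentence)
  f <- list()
  add <- function(name, value = 1) f[[feat_name(name)]] <<- value
  bump <- function(name) {
    name <- feat_name(name)
    f[[name]] <<- (if (is.null(f[[name]])) 0 else f[[name]]) + 1
  }

  add(paste0("time_type=", tolower(time$time_type)))
  add(paste0("event_type=", tolower(event$event_type)))
  add(paste0("event_polarity=", tolower(event$polarity)))
  add(paste0("event_modality=", tolower(event$modality)))

  ttoks <- tolower(tok$text[trng[1]:trng[2]])
  etoks <- tolower(tok$text[erng[1]:erng[2]])
  for (w in unique(ttoks)) add(paste0("t_tok=", w))
  for (w in unique(etoks)) add(paste0("e_tok=", w))

  ctx <- function(rng, prefix) {
    for (k in 1:3) {
      i <- rng[1] - k
      if (i >= 1) add(paste0(prefix, "_prev", k, "=", tolower(tok$text[i])))
      j <- rng[2] + k
      if (j <= n) add(paste0(prefix, "_next", k, "=", tolower(tok$text[j])))
    }
  }
  ctx(trng, "t")
  ctx(erng, "e")

  lo <- min(trng[2], erng[2]) + 1L
  hi <- max(trng[1], erng[1]) - 1L
  between <- if (lo <= hi) lo:hi else integer(0)
  add("btw_count", length(between))
  for (w in unique(tolower(tok$text[between]))) add(paste0("btw_tok=", w))
  add("btw_punct", sum(grepl(PUNCT_RE, tok$text[between])))

  if (!anyNA(tok$pos)) {
    for (p in unique(tok$pos[trng[1]:trng[2]])) add(paste0("t_pos=", p))
    for (p in unique(tok$pos[erng[1]:erng[2]])) add(paste0("e_pos=", p))
    span_lo <- min(trng[1], erng[1])
    span_hi <- max(trng[2], erng[2])
    for (i in which(grepl("^(V|MD)", tok$pos))) {
      posn <- if (i < span_lo) "before" else if (i > span_hi) "after" else
        "between"
      bump(paste0("verb_", verb_tense(tok$pos[i]), "_", posn))
    }
  }

  if (!is.na(sentence$section_label)) {
    add(paste0("section=", tolower(sentence$section_label)))
  }
  if (sentence$starts_with_enumeration) add("sent_enum_start")
  if (sentence$ends_with_colon) add("sent_colon_end")

  if (nrow(sentence$deps)) {
    d <- sentence$deps
    th <- trng[2]
    eh <- erng[2]
    ta <- dep_ancestors(d, th, n)
    ea <- dep_ancestors(d, eh, n)
    common <- intersect(ta, ea)
    if (length(common)) {
      anc <- common[1]
      if (!is.na(tok$pos[anc])) add(paste0("dep_anc_pos=", tok$pos[anc]))
      add(paste0("dep_anc_tok=", tolower(tok$text[anc])))
      path <- union(ta[seq_len(match(anc, ta))], ea[seq_len(match(anc, ea))])
      path <- setdiff(path, c(trng[1]:trng[2], erng[1]:erng[2]))
      if (any(grepl("^NN", tok$pos[path]))) add("dep_path_noun")
    }
  }

  if (length(sentence$frames)) {
    tpred <- NA_integer_
    epred <- NA_integer_
    for (fr in sentence$frames) {
      spans <- fr$args
      if (is.null(spans) || !nrow(spans)) next
      if (is.na(tpred) &&
          any(spans$from <= trng[1] & spans$to >= trng[2])) {
        tpred <- fr$pred
      }
      if (is.na(epred) &&
          any(spans$from <= erng[1] & spans$to >= erng[2])) {
        epred <- fr$pred
      }
    }
    if (!is.na(tpred)) add(paste0("t_pred=", tolower(tok$text[tpred])))
    if (!is.na(epred)) add(paste0("e_pred=", tolower(tok$text[epred])))
    if (!is.na(tpred) && !is.na(epred) && tpred == epred) add("same_pred")
  }

  if (!is.null(decision)) {
    if (decision$is_direct) add("rule_direct")
    add(paste0("rule_rationale=", tolower(decision$rationale)))
    add(paste0("rule_exception=", tolower(decision$exception_used)))
  }

  unlist(f)
}

# Stack sparse feature vectors into a dense matrix over `feature_names`
# (union of names when NULL). Unknown features are dropped.
build_feature_matrix <- function(features, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- sort(unique(unlist(lapply(features, names))))
  }
  mat <- matrix(0, nrow = length(features), ncol = length(feature_names),
                dimnames = list(NULL, feature_names))
  for (i in seq_along(features)) {
    v <- features[[i]]
    keep <- names(v) %in% feature_names
    if (any(keep)) mat[i, names(v)[keep]] <- v[keep]
  }
  mat
}
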