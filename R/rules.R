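# Deterministic direct / non-direct decision for intra-sentential
# time-event pairs.
#
# A pair is DIRECT when either
#   1) the phrase headed by one mention modifies the phrase headed by the
#      other (forming a bigger grammatical element), or
#   2) both mentions head phrases that are arguments or adjuncts of the same
#      predicate (at least one an argument),
# where "headed by" admits three exception cases that widen a mention's
# phrasal projection even though the mention is not the literal head:
#   PP_CASE              the mention heads the NP inside a PP (the
#                        preposition being the PP's head);
#   COORD_CASE           the mention heads one coordinate of a coordinated
#                        phrase;
#   TYPE_PRESERVING_CASE the mention heads a phrase embedded in a
#                        type-preserving phrase from the lexicon.
# Exception widening is chained to a fixed point, so e.g. a type-preserving
# phrase can wrap a PP-widened projection.

CLAUSE_LIKE_LABELS <- c("S", "SBAR", "SINV", "SQ", "FRAG", "ROOT", "TOP",
                        "VP", "UCP", "")
PHRASE_LABELS <- c("NP", "NX", "NML", "PP", "ADVP", "ADJP", "QP", "WHNP")
NP_LIKE_LABELS <- c("NP", "NX", "NML", "QP", "WHNP")

#' Options controlling the direct-relation rule engine
#'
#' @param pp_exception,coord_exception,type_preserving_exception Enable the
#'   three projection-widening exception cases. Disabling an exception can
#'   only turn direct decisions into non-direct ones, never the reverse.
#' @param dependency_fallback When a sentence carries no predicate frames,
#'   approximate the shared-predicate rule by requiring both mention head
#'   tokens to attach to the same verb with a single dependency edge.
#'   Decisions made this way are flagged.
#' @return A list of class `rule_options`.
#' @export
rule_options <- function(pp_exception = TRUE, coord_exception = TRUE,
                         type_preserving_exception = TRUE,
                         dependency_fallback = TRUE) {
  structure(list(pp_exception = isTRUE(pp_exception),
                 coord_exception = isTRUE(coord_exception),
                 type_preserving_exception = isTRUE(type_preserving_exception),
                 dependency_fallback = isTRUE(dependency_fallback)),
            class = "rule_options")
}

# Token range (1-based, inclusive) covered by a mention's character span.
mention_token_range <- function(mention, sentence) {
  tok <- sentence$tokens
  hit <- which(tok$start < mention$end & tok$end > mention$start)
  if (!length(hit)) {
    stop("mention '", mention$id, "' covers no token of its sentence",
         call. = FALSE)
  }
  c(min(hit), max(hit))
}

# TRUE when `node` coordinates >= 2 children labelled `label`: either an
# explicit conjunction (CC/CONJP) sits between two of them, or a comma does
# and there are >= 3 coordinates (a comma with only two same-label children
# is treated as apposition or adjunction, not coordination).
is_coordinated <- function(node, label) {
  labs <- vapply(node$children, function(ch) ch$label, character(1))
  same <- which(labs == label)
  if (length(same) < 2) return(FALSE)
  between <- function(set) {
    any(vapply(set, function(j) any(same < j) && any(same > j), logical(1)))
  }
  between(which(labs %in% c("CC", "CONJP"))) ||
    (length(same) >= 3 && between(which(labs == ",")))
}

# Match a type-preserving template at `anc`: its leaves must be the template's
# pre tokens, then a placeholder gap equal to [gfrom, gto], then the post
# tokens, and the mention must satisfy the placeholder class.
tp_template_match <- function(anc, gfrom, gto, mention, sentence, lexicon) {
  if (!nrow(lexicon)) return(FALSE)
  toks <- tolower(sentence$tokens$text)
  for (i in seq_len(nrow(lexicon))) {
    if (!mention_matches_class(mention, lexicon$class[i])) next
    pre <- lexicon$pre[[i]]
    post <- lexicon$post[[i]]
    if (anc$from + length(pre) != gfrom) next
    if (anc$to - length(post) != gto) next
    if (length(pre) &&
        !identical(toks[anc$from:(gfrom - 1L)], pre)) next
    if (length(post) &&
        !identical(toks[(gto + 1L):anc$to], post)) next
    return(TRUE)
  }
  FALSE
}

#' Maximal head projection of a mention
#'
#' Finds the largest constituent whose lexical head lies inside the mention,
#' then widens it through the enabled exception cases (iterated to a fixed
#' point). The returned chain of constituents — from the smallest covering
#' node up to the final projection — is what the modification detector
#' compares.
#'
#' @param mention One mention row of the document.
#' @param sentence The mention's [annotated_sentence()] (must carry a tree).
#' @param lexicon A [type_preserving_lexicon()].
#' @param head_table A [default_head_table()].
#' @param options A [rule_options()].
#' @return List with elements `node` (the projection), `path` (child-index
#'   path from the root), `chain` (list of `list(path, parent_label)` for
#'   every node from smallest covering node to projection), `exceptions`
#'   (character vector of exception cases used), `aligned` (FALSE when the
#'   mention's tokens cross brackets and only a covering node exists), and
#'   `head_token` (token index used for dependency features).
#' @export
maximal_head_projection <- function(mention, sentence,
                                    lexicon = type_preserving_lexicon(),
                                    head_table = default_head_table(),
                                    options = rule_options()) {
  rng <- mention_token_range(mention, sentence)
  project_range(rng[1], rng[2], mention, sentence, lexicon, head_table,
                options)
}

project_range <- function(tfrom, tto, mention, sentence, lexicon, head_table,
                          options) {
  cp <- covering_path(sentence$tree, tfrom, tto)
  nodes <- cp$nodes
  k <- length(nodes)
  minimal <- nodes[[k]]
  aligned <- minimal$from == tfrom && minimal$to == tto
  head_tok <- lexical_head_index(minimal, head_table)
  if (head_tok < tfrom || head_tok > tto) head_tok <- tto
  climb <- function(j) {
    while (j > 1) {
      h <- lexical_head_index(nodes[[j - 1L]], head_table)
      if (h >= tfrom && h <= tto) j <- j - 1L else break
    }
    j
  }
  j <- climb(k)
  used <- character(0)
  repeat {
    widened <- FALSE
    node <- nodes[[j]]
    parent <- if (j > 1) nodes[[j - 1L]] else NULL
    if (options$pp_exception && !is.null(parent) &&
        parent$label == "PP" && node$label %in% NP_LIKE_LABELS) {
      j <- j - 1L
      used <- c(used, "PP_CASE")
      widened <- TRUE
    }
    if (!widened && options$coord_exception && !is.null(parent) &&
        is_coordinated(parent, node$label)) {
      j <- j - 1L
      used <- c(used, "COORD_CASE")
      widened <- TRUE
    }
    if (!widened && options$type_preserving_exception && j > 1) {
      for (a in rev(seq_len(j - 1L))) {
        hit <- tp_template_match(nodes[[a]], node$from, node$to, mention,
                                 sentence, lexicon) ||
          tp_template_match(nodes[[a]], tfrom, tto, mention, sentence,
                            lexicon)
        if (hit) {
          j <- a
          used <- c(used, "TYPE_PRESERVING_CASE")
          widened <- TRUE
          break
        }
      }
    }
    if (widened) j <- climb(j) else break
  }
  chain <- lapply(seq(j, k), function(d) {
    list(path = cp$idx[seq_len(d - 1L)],
         parent_label = if (d > 1) nodes[[d - 1L]]$label else "ROOT")
  })
  list(node = nodes[[j]], path = cp$idx[seq_len(j - 1L)], chain = chain,
       minimal_path = cp$idx, exceptions = unique(used), aligned = aligned,
       head_token = head_tok)
}

is_path_prefix <- function(a, b) {
  length(a) < length(b) && identical(b[seq_along(a)], a)
}

#' Test whether two head projections stand in a modification configuration
#'
#' One projection modifies the other when some constituent of one mention's
#' projection chain is a direct child of, or a sibling of, a constituent of
#' the other's chain — siblings only under a phrase-level parent (NP, ADVP,
#' PP, ...), since co-children of a clause or VP are related through the verb
#' (the shared-predicate rule), not through modification.
#'
#' @param proj_a,proj_b Projections from [maximal_head_projection()] over the
#'   same sentence tree.
#' @return `TRUE` or `FALSE`.
#' @export
detect_modification <- function(proj_a, proj_b) {
  for (a in proj_a$chain) {
    for (b in proj_b$chain) {
      la <- length(a$path)
      lb <- length(b$path)
      if (lb == la + 1L && is_path_prefix(a$path, b$path)) return(TRUE)
      if (la == lb + 1L && is_path_prefix(b$path, a$path)) return(TRUE)
      if (la == lb && la >= 1L &&
          identical(a$path[-la], b$path[-lb]) &&
          a$path[la] != b$path[lb] &&
          !a$parent_label %in% CLAUSE_LIKE_LABELS) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Find a predicate shared by a time expression and an event mention
#'
#' Returns the predicate token index of a frame in which each mention's head
#' projection covers a full argument/adjunct span containing the mention
#' (i.e. the mention, possibly via an exception case, heads the phrase
#' serving that role), with at least one of the two spans an ARGUMENT. When
#' the sentence has no frames and the dependency fallback is enabled, a verb
#' to which both mention head tokens attach by one dependency edge is
#' accepted instead and flagged.
#'
#' @param time,event Mention rows.
#' @param sentence The [annotated_sentence()].
#' @param time_proj,event_proj Projections from [maximal_head_projection()];
#'   computed when omitted.
#' @inheritParams maximal_head_projection
#' @return List with `pred` (token index, or `NA` when no shared predicate)
#'   and `fallback` (TRUE when the dependency approximation was used).
#' @export
detect_shared_predicate <- function(time, event, sentence,
                                    time_proj = NULL, event_proj = NULL,
                                    lexicon = type_preserving_lexicon(),
                                    head_table = default_head_table(),
                                    options = rule_options()) {
  if (is.null(time_proj)) {
    time_proj <- maximal_head_projection(time, sentence, lexicon, head_table,
                                         options)
  }
  if (is.null(event_proj)) {
    event_proj <- maximal_head_projection(event, sentence, lexicon,
                                          head_table, options)
  }
  trng <- mention_token_range(time, sentence)
  erng <- mention_token_range(event, sentence)
  for (f in sentence$frames) {
    spans <- f$args
    if (is.null(spans) || !nrow(spans)) next
    covers <- function(rng, proj) {
      spans$from <= rng[1] & spans$to >= rng[2] &
        spans$from >= proj$node$from & spans$to <= proj$node$to
    }
    t_rows <- which(covers(trng, time_proj))
    e_rows <- which(covers(erng, event_proj))
    if (length(t_rows) && length(e_rows) &&
        (any(spans$kind[t_rows] == "ARGUMENT") ||
         any(spans$kind[e_rows] == "ARGUMENT"))) {
      return(list(pred = f$pred, fallback = FALSE))
    }
  }
  if (!length(sentence$frames) && options$dependency_fallback &&
      nrow(sentence$deps)) {
    d <- sentence$deps
    vt <- d$head[d$dep == time_proj$head_token]
    ve <- d$head[d$dep == event_proj$head_token]
    shared <- intersect(vt, ve)
    shared <- shared[shared > 0]
    shared <- shared[grepl("^(V|MD)", sentence$tokens$pos[shared])]
    if (length(shared)) {
      return(list(pred = shared[1], fallback = TRUE))
    }
  }
  list(pred = NA_integer_, fallback = FALSE)
}

# Does any single frame contain both mentions inside argument/adjunct spans,
# ignoring the head requirement? Used only to separate NOT_HEAD from
# NO_SYNTACTIC_LINK in the rationale.
frame_covers_both <- function(sentence, trng, erng) {
  for (f in sentence$frames) {
    spans <- f$args
    if (is.null(spans) || !nrow(spans)) next
    t_in <- any(spans$from <= trng[1] & spans$to >= trng[2])
    e_in <- any(spans$from <= erng[1] & spans$to >= erng[2])
    if (t_in && e_in) return(TRUE)
  }
  FALSE
}

pick_exception <- function(exceptions) {
  for (e in c("TYPE_PRESERVING_CASE", "COORD_CASE", "PP_CASE")) {
    if (e %in% exceptions) return(e)
  }
  "NONE"
}

#' Decide whether a time-event pair forms a direct temporal relation
#'
#' Pure function of the sentence analyses: the pair is direct when the two
#' head projections stand in a modification configuration, or when both
#' mentions (head requirement and exceptions applied) fill roles of the same
#' predicate. Non-direct pairs are explained as `NOT_HEAD` (a syntactic link
#' exists but a mention fails the head requirement) or `NO_SYNTACTIC_LINK`.
#'
#' @param time,event Mention rows from the same sentence.
#' @param sentence The pair's [annotated_sentence()].
#' @inheritParams maximal_head_projection
#' @return A list of class `direct_decision` with fields `is_direct`,
#'   `rationale` (`MODIFICATION`, `SAME_PREDICATE`, `NOT_HEAD`,
#'   `NO_SYNTACTIC_LINK`), `exception_used`, `exceptions` (all exception
#'   cases used by either projection), `predicate` (token index or `NA`),
#'   `dependency_fallback` and `aligned`.
#' @export
classify_pair <- function(time, event, sentence,
                          lexicon = type_preserving_lexicon(),
                          head_table = default_head_table(),
                          options = rule_options()) {
  tp <- maximal_head_projection(time, sentence, lexicon, head_table, options)
  ep <- maximal_head_projection(event, sentence, lexicon, head_table, options)
  exceptions <- union(tp$exceptions, ep$exceptions)
  res <- list(is_direct = FALSE, rationale = "NO_SYNTACTIC_LINK",
              exception_used = pick_exception(exceptions),
              exceptions = exceptions, predicate = NA_integer_,
              dependency_fallback = FALSE,
              aligned = tp$aligned && ep$aligned)
  if (detect_modification(tp, ep)) {
    res$is_direct <- TRUE
    res$rationale <- "MODIFICATION"
  } else {
    sp <- detect_shared_predicate(time, event, sentence, tp, ep, lexicon,
                                  head_table, options)
    if (!is.na(sp$pred)) {
      res$is_direct <- TRUE
      res$rationale <- "SAME_PREDICATE"
      res$predicate <- sp$pred
      res$dependency_fallback <- sp$fallback
    } else {
      trng <- mention_token_range(time, sentence)
      erng <- mention_token_range(event, sentence)
      common <- 0L
      tpath <- tp$minimal_path
      epath <- ep$minimal_path
      while (common < length(tpath) && common < length(epath) &&
             tpath[common + 1L] == epath[common + 1L]) {
        common <- common + 1L
      }
      lca <- node_at_path(sentence$tree, tpath[seq_len(common)])
      if (frame_covers_both(sentence, trng, erng) ||
          lca$label %in% PHRASE_LABELS) {
        res$rationale <- "NOT_HEAD"
      }
    }
  }
  class(res) <- "direct_decision"
  res
}

#' Apply the rule engine to every candidate pair of a document
#'
#' @param doc A [new_document()] whose sentences carry trees.
#' @inheritParams maximal_head_projection
#' @return Data frame with one row per candidate pair: `doc_id`,
#'   `sentence_index`, `time_id`, `event_id`, `is_direct`, `rationale`,
#'   `exception_used`, `exceptions` (comma-joined), `dependency_fallback`.
#' @export
classify_candidates <- function(doc, lexicon = type_preserving_lexicon(),
                                head_table = default_head_table(),
                                options = rule_options()) {
  cand <- enumerate_candidates(doc)
  n <- nrow(cand)
  out <- data.frame(doc_id = rep(doc$doc_id, n),
                    cand,
                    is_direct = logical(n), rationale = character(n),
                    exception_used = character(n), exceptions = character(n),
                    dependency_fallback = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- doc$sentences[[cand$sentence_index[i]]]
    dec <- classify_pair(mention_row(doc, cand$time_id[i]),
                         mention_row(doc, cand$event_id[i]),
                         s, lexicon, head_table, options)
    out$is_direct[i] <- dec$is_direct
    out$rationale[i] <- dec$rationale
    out$exception_used[i] <- dec$exception_used
    out$exceptions[i] <- paste(dec$exceptions, collapse = ",")
    out$dependency_fallback[i] <- dec$dependency_fallback
  }
  out
}
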