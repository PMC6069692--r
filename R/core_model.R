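# Core domain types: mentions, annotated sentences, documents, relation sets,
# and candidate-pair enumeration.
#
# Conventions used throughout the package:
#  * character offsets are 0-based, half-open, over the raw document text;
#  * token indices are 1-based and inclusive (R convention);
#  * sentence indices are 1-based.

REL_TYPES <- c("BEFORE", "AFTER", "OVERLAP")
TIME_TYPES <- c("DATE", "TIME", "DURATION", "FREQUENCY")
EVENT_TYPES <- c("PROBLEM", "TEST", "TREATMENT", "OTHER")
CLASS_LABELS <- c("OVERLAP", "BEFORE", "AFTER", "NO_RELATION")

#' Create a time-expression mention
#'
#' @param id Mention identifier, unique within its document.
#' @param start,end Character span over the raw document text (0-based,
#'   half-open).
#' @param text Surface string; must equal the document substring at the span.
#' @param time_type One of `"DATE"`, `"TIME"`, `"DURATION"`, `"FREQUENCY"`.
#' @param sentence_index 1-based sentence index, or `NA` to be resolved
#'   against sentence spans by [new_document()].
#' @return A one-row data frame in the package's mention layout.
#' @export
time_mention <- function(id, start, end, text, time_type, sentence_index = NA_integer_) {
  time_type <- match.arg(toupper(time_type), TIME_TYPES)
  new_mention(id, start, end, text, "TIME", sentence_index,
              time_type = time_type)
}

#' Create an event mention
#'
#' @inheritParams time_mention
#' @param event_type One of `"PROBLEM"`, `"TEST"`, `"TREATMENT"`, `"OTHER"`.
#'   Schema types outside the three clinical categories map to `"OTHER"`.
#' @param polarity,modality Free-string attributes carried through from the
#'   annotation source.
#' @return A one-row data frame in the package's mention layout.
#' @export
event_mention <- function(id, start, end, text, event_type,
                          polarity = "POS", modality = "FACTUAL",
                          sentence_index = NA_integer_) {
  event_type <- toupper(event_type)
  if (!event_type %in% EVENT_TYPES) event_type <- "OTHER"
  new_mention(id, start, end, text, "EVENT", sentence_index,
              event_type = event_type, polarity = polarity, modality = modality)
}

new_mention <- function(id, start, end, text, category, sentence_index,
                        time_type = NA_character_, event_type = NA_character_,
                        polarity = NA_character_, modality = NA_character_) {
  if (start >= end) {
    stop("mention '", id, "': span start must be < end", call. = FALSE)
  }
  data.frame(
    id = as.character(id), start = as.integer(start), end = as.integer(end),
    text = as.character(text), category = category,
    sentence_index = as.integer(sentence_index),
    time_type = time_type, event_type = event_type,
    polarity = polarity, modality = modality,
    stringsAsFactors = FALSE
  )
}

empty_mentions <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             text = character(), category = character(),
             sentence_index = integer(), time_type = character(),
             event_type = character(), polarity = character(),
             modality = character(), stringsAsFactors = FALSE)
}

#' Create a per-sentence linguistic analysis record
#'
#' Sentence analyses (tokens, parse tree, dependencies, predicate frames) are
#' inputs to the rule engine; the package does not run a parser.
#'
#' @param start,end Character span of the sentence (0-based, half-open).
#' @param tokens Data frame with columns `text`, `start`, `end`, `pos`.
#' @param tree A constituency tree ([parse_bracketed_tree()]) whose leaves
#'   align one-to-one with `tokens`, or `NULL` when no parse is available.
#' @param deps Data frame with columns `head`, `dep`, `label`; token indices
#'   are 1-based, `head = 0` marks the root.
#' @param frames List of predicate frames, each
#'   `list(pred = <token index>, args = data.frame(role, from, to, kind))`
#'   with `kind` in `ARGUMENT`/`ADJUNCT` and `from`/`to` inclusive token
#'   indices.
#' @param section_label Section the sentence belongs to (e.g. `"HOSPITAL
#'   COURSE"`), or `NA`.
#' @param starts_with_enumeration,ends_with_colon Sentence-type flags.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(start, end, tokens, tree = NULL,
                               deps = NULL, frames = list(),
                               section_label = NA_character_,
                               starts_with_enumeration = FALSE,
                               ends_with_colon = FALSE) {
  if (is.null(deps)) {
    deps <- data.frame(head = integer(), dep = integer(), label = character(),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("text", "start", "end", "pos") %in% names(tokens)))
  if (!is.null(tree)) {
    nl <- length(tree_leaves(tree))
    if (nl != nrow(tokens)) {
      stop("tree has ", nl, " leaves but sentence has ", nrow(tokens),
           " tokens", call. = FALSE)
    }
  }
  structure(
    list(start = as.integer(start), end = as.integer(end), tokens = tokens,
         tree = tree, deps = deps, frames = frames,
         section_label = section_label,
         starts_with_enumeration = isTRUE(starts_with_enumeration),
         ends_with_colon = isTRUE(ends_with_colon)),
    class = "annotated_sentence"
  )
}

#' Assemble a document from text, sentence analyses and mentions
#'
#' Mentions with an `NA` sentence index are resolved against the sentence
#' spans; a mention crossing a sentence boundary is assigned to the sentence
#' containing its start, with a warning.
#'
#' @param doc_id Document identifier.
#' @param text Raw document text.
#' @param sentences List of [annotated_sentence()] records, ordered and
#'   non-overlapping.
#' @param mentions Mention data frame (rows from [time_mention()] /
#'   [event_mention()]).
#' @param relations Optional gold [relation_graph()].
#' @return An object of class `dtr_document`.
#' @export
new_document <- function(doc_id, text, sentences, mentions = empty_mentions(),
                         relations = NULL) {
  if (length(sentences)) {
    ss <- vapply(sentences, function(s) s$start, integer(1))
    se <- vapply(sentences, function(s) s$end, integer(1))
    if (is.unsorted(ss) || any(ss[-1] < se[-length(se)])) {
      stop("sentence spans must be ordered and non-overlapping", call. = FALSE)
    }
    for (i in seq_len(nrow(mentions))) {
      m <- mentions[i, ]
      hit <- which(ss <= m$start & m$start < se)
      if (!length(hit)) {
        if (is.na(m$sentence_index)) {
          stop("mention '", m$id, "' lies outside every sentence span",
               call. = FALSE)
        }
      } else {
        if (m$end > se[hit[1]]) {
          warning("mention '", m$id,
                  "' crosses a sentence boundary; assigned to sentence ",
                  hit[1], call. = FALSE)
        }
        mentions$sentence_index[i] <- hit[1]
      }
    }
  }
  if (anyDuplicated(mentions$id)) {
    stop("duplicate mention ids: ",
         paste(unique(mentions$id[duplicated(mentions$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- if (nrow(mentions)) {
    which(substring(text, mentions$start + 1L, mentions$end) !=
            mentions$text)
  } else {
    integer(0)
  }
  if (length(bad)) {
    stop("mention text does not match document substring for: ",
         paste(mentions$id[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(relations)) relations <- relation_graph()
  structure(list(doc_id = doc_id, text = text, sentences = sentences,
                 mentions = mentions, relations = relations),
            class = "dtr_document")
}

#' @export
print.dtr_document <- function(x, ...) {
  cat("<dtr_document> ", x$doc_id, ": ", length(x$sentences), " sentences, ",
      nrow(x$mentions), " mentions, ", nrow(x$relations), " relations\n",
      sep = "")
  invisible(x)
}

mention_row <- function(doc, id) {
  i <- match(id, doc$mentions$id)
  if (is.na(i)) {
    stop("unknown mention id '", id, "' in document '", doc$doc_id, "'",
         call. = FALSE)
  }
  doc$mentions[i, ]
}

#' Construct a set of temporal relations
#'
#' A relation graph is a deduplicated set of ordered
#' (source, target, type) links with type in `BEFORE`/`AFTER`/`OVERLAP`.
#'
#' @param source,target Mention id vectors (`source != target` elementwise).
#' @param type Relation types.
#' @return A data frame of class `relation_graph`, sorted deterministically.
#' @export
relation_graph <- function(source = character(), target = character(),
                           type = character()) {
  type <- toupper(as.character(type))
  bad <- setdiff(unique(type), REL_TYPES)
  if (length(bad)) {
    stop("unknown relation type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  source <- as.character(source)
  target <- as.character(target)
  if (any(source == target)) {
    stop("self-relations are not allowed", call. = FALSE)
  }
  key <- paste(source, target, type, sep = "\r")
  keep <- which(!duplicated(key))
  keep <- keep[order(key[keep])]
  g <- data.frame(source = source[keep], target = target[keep],
                  type = type[keep], stringsAsFactors = FALSE)
  rownames(g) <- NULL
  class(g) <- c("relation_graph", "data.frame")
  g
}

as_relation_graph <- function(df) {
  relation_graph(df$source, df$target, df$type)
}

graphs_equal <- function(a, b) {
  key <- function(g) sort(paste(g$source, g$target, g$type, sep = "\r"))
  identical(key(a), key(b))
}

#' Enumerate intra-sentential time-event candidate pairs
#'
#' Returns every (time expression, event mention) pair sharing a sentence,
#' which is the candidate space for direct temporal relations; cross-sentence
#' pairs and pairs of like-category mentions are never candidates.
#'
#' @param doc A [new_document()].
#' @return Data frame with columns `sentence_index`, `time_id`, `event_id`,
#'   ordered by (sentence index, time start, event start).
#' @export
enumerate_candidates <- function(doc) {
  m <- doc$mentions
  if (nrow(m) && anyNA(m$sentence_index)) {
    bad <- m$id[is.na(m$sentence_index)]
    stop("mention(s) with unresolved sentence index: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sentence_index = integer(), time_id = character(),
                    event_id = character(), stringsAsFactors = FALSE)
  if (!nrow(m)) return(out)
  for (s in sort(unique(m$sentence_index))) {
    tt <- m[m$sentence_index == s & m$category == "TIME", , drop = FALSE]
    ee <- m[m$sentence_index == s & m$category == "EVENT", , drop = FALSE]
    if (!nrow(tt) || !nrow(ee)) next
    tt <- tt[order(tt$start, tt$id), , drop = FALSE]
    ee <- ee[order(ee$start, ee$id), , drop = FALSE]
    grid <- expand.grid(e = seq_len(nrow(ee)), t = seq_len(nrow(tt)))
    out <- rbind(out, data.frame(sentence_index = s,
                                 time_id = tt$id[grid$t],
                                 event_id = ee$id[grid$e],
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$sentence_index,
                   match(out$time_id, m$id),
                   match(out$event_id, m$id)), , drop = FALSE]
  ts <- m$start[match(out$time_id, m$id)]
  es <- m$start[match(out$event_id, m$id)]
  out <- out[order(out$sentence_index, ts, es), , drop = FALSE]
  rownames(out) <- NULL
  out
}
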