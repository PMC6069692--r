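# Standoff XML annotation dialect (TIMEX3 / EVENT / TLINK elements) and the
# prediction writer. The dialect mirrors the 2012-era community format:
#
#   <TemporalAnnotation doc_id="...">
#     <TEXT>raw document text</TEXT>
#     <TAGS>
#       <TIMEX3 id="T0" start="0" end="10" text="..." type="DATE"/>
#       <EVENT  id="E0" start="12" end="20" text="..." type="PROBLEM"
#               polarity="POS" modality="FACTUAL"/>
#       <TLINK  id="TL0" fromID="T0" toID="E0" type="OVERLAP"/>
#     </TAGS>
#   </TemporalAnnotation>
#
# Character offsets are 0-based and half-open over the raw text. TLINK type
# labels are normalized through an explicit, config-editable map; labels
# outside the map are a hard error, never a silent skip.

#' Default TLINK label map
#'
#' Collapses the extended TLINK label inventory onto the three canonical
#' types. `SIMULTANEOUS` and `DURING` denote coextension or containment and
#' map to `OVERLAP`; `BEFORE_OVERLAP` and `ENDED_BY` entail that the source
#' starts before the target and map to `BEFORE`; `BEGUN_BY` entails the
#' source extends past the target's start and maps to `AFTER`. Edit or
#' replace the map to change the policy; unmapped labels raise an error.
#'
#' @return Named character vector: input label -> canonical type.
#' @export
default_tlink_label_map <- function() {
  c(BEFORE = "BEFORE", AFTER = "AFTER", OVERLAP = "OVERLAP",
    SIMULTANEOUS = "OVERLAP", DURING = "OVERLAP",
    BEFORE_OVERLAP = "BEFORE", ENDED_BY = "BEFORE", BEGUN_BY = "AFTER")
}

map_tlink_labels <- function(labels, label_map) {
  labels <- toupper(labels)
  mapped <- label_map[labels]
  if (anyNA(mapped)) {
    stop("unmappable TLINK label(s): ",
         paste(unique(labels[is.na(mapped)]), collapse = ", "),
         call. = FALSE)
  }
  unname(mapped)
}

#' Read an annotated document
#'
#' Parses the annotation XML and, when given, the sidecar sentence-analysis
#' file ([read_sidecar()]). Counts of parsed TIMEX3/EVENT/TLINK records are
#' attached as the `io_counts` attribute; no record is ever silently dropped.
#' Missing sidecar section labels are filled from the section-header lexicon
#' applied to the raw text.
#'
#' @param annotation_path Path to the annotation XML file.
#' @param analysis_path Optional path to the sidecar analysis file; without
#'   it, sentences are derived by a line-based splitter and carry no trees.
#' @param label_map TLINK label map ([default_tlink_label_map()]).
#' @param section_lexicon Header lexicon for section back-fill.
#' @return A [new_document()].
#' @export
read_document <- function(annotation_path, analysis_path = NULL,
                          label_map = default_tlink_label_map(),
                          section_lexicon = section_header_lexicon()) {
  xml <- xml2::read_xml(annotation_path)
  doc_id <- xml2::xml_attr(xml, "doc_id")
  if (is.na(doc_id)) doc_id <- basename(annotation_path)
  text_node <- xml2::xml_find_first(xml, "./TEXT")
  text <- if (inherits(text_node, "xml_missing")) "" else
    xml2::xml_text(text_node)

  timex <- xml2::xml_find_all(xml, ".//TIMEX3")
  events <- xml2::xml_find_all(xml, ".//EVENT")
  tlinks <- xml2::xml_find_all(xml, ".//TLINK")

  mentions <- empty_mentions()
  for (nd in timex) {
    mentions <- rbind(mentions, time_mention(
      id = xml2::xml_attr(nd, "id"),
      start = as.integer(xml2::xml_attr(nd, "start")),
      end = as.integer(xml2::xml_attr(nd, "end")),
      text = xml2::xml_attr(nd, "text"),
      time_type = xml2::xml_attr(nd, "type")))
  }
  for (nd in events) {
    pol <- xml2::xml_attr(nd, "polarity")
    mod <- xml2::xml_attr(nd, "modality")
    mentions <- rbind(mentions, event_mention(
      id = xml2::xml_attr(nd, "id"),
      start = as.integer(xml2::xml_attr(nd, "start")),
      end = as.integer(xml2::xml_attr(nd, "end")),
      text = xml2::xml_attr(nd, "text"),
      event_type = xml2::xml_attr(nd, "type"),
      polarity = if (is.na(pol)) "POS" else pol,
      modality = if (is.na(mod)) "FACTUAL" else mod))
  }

  rel <- relation_graph()
  if (length(tlinks)) {
    from <- xml2::xml_attr(tlinks, "fromID")
    to <- xml2::xml_attr(tlinks, "toID")
    type <- map_tlink_labels(xml2::xml_attr(tlinks, "type"), label_map)
    miss <- setdiff(unique(c(from, to)), mentions$id)
    if (length(miss)) {
      stop("TLINK references unknown mention id(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    rel <- relation_graph(from, to, type)
  }

  sentences <- if (!is.null(analysis_path)) {
    read_sidecar(analysis_path)
  } else {
    basic_sentences(text)
  }
  if (length(sentences)) {
    secs <- detect_sections(text, section_lexicon)
    for (i in seq_along(sentences)) {
      if (is.na(sentences[[i]]$section_label)) {
        sentences[[i]]$section_label <-
          section_for_position(secs, sentences[[i]]$start)
      }
    }
  }
  doc <- new_document(doc_id, text, sentences, mentions, rel)
  attr(doc, "io_counts") <- c(timex3 = length(timex), event = length(events),
                              tlink = length(tlinks))
  doc
}

# Whitespace-tokenized, newline-split sentences for documents without a
# sidecar; enough for candidate enumeration and the closure filter, not for
# the rule engine.
basic_sentences <- function(text) {
  if (!nzchar(text)) return(list())
  lines <- strsplit(paste0(text, "\n"), "\n", fixed = TRUE)[[1]]
  starts <- cumsum(c(0L, nchar(lines) + 1L))[seq_along(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    toks <- gregexpr("[^[:space:]]+", lines[i])[[1]]
    tdf <- data.frame(
      text = regmatches(lines[i], gregexpr("[^[:space:]]+", lines[i]))[[1]],
      start = starts[i] + as.integer(toks) - 1L,
      end = starts[i] + as.integer(toks) - 1L +
        attr(toks, "match.length"),
      pos = NA_character_, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- annotated_sentence(
      start = starts[i], end = starts[i] + nchar(lines[i]),
      tokens = tdf,
      ends_with_colon = grepl(":\\s*$", lines[i]))
  }
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a full annotated document
#'
#' Emits text, mentions and relations in the dialect read by
#' [read_document()] (round-trip safe).
#'
#' @param doc A [new_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(doc, path) {
  m <- doc$mentions
  lines <- c(sprintf("<TemporalAnnotation doc_id=\"%s\">",
                     xml_escape(doc$doc_id)),
             paste0("<TEXT>", xml_escape(doc$text), "</TEXT>"),
             "<TAGS>")
  tm <- m[m$category == "TIME", , drop = FALSE]
  for (i in seq_len(nrow(tm))) {
    lines <- c(lines, sprintf(
      "<TIMEX3 id=\"%s\" start=\"%d\" end=\"%d\" text=\"%s\" type=\"%s\"/>",
      xml_escape(tm$id[i]), tm$start[i], tm$end[i], xml_escape(tm$text[i]),
      tm$time_type[i]))
  }
  em <- m[m$category == "EVENT", , drop = FALSE]
  for (i in seq_len(nrow(em))) {
    lines <- c(lines, sprintf(
      paste0("<EVENT id=\"%s\" start=\"%d\" end=\"%d\" text=\"%s\"",
             " type=\"%s\" polarity=\"%s\" modality=\"%s\"/>"),
      xml_escape(em$id[i]), em$start[i], em$end[i], xml_escape(em$text[i]),
      em$event_type[i], xml_escape(em$polarity[i]),
      xml_escape(em$modality[i])))
  }
  lines <- c(lines, tlink_lines(doc$relations), "</TAGS>",
             "</TemporalAnnotation>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

tlink_lines <- function(graph) {
  if (!nrow(graph)) return(character(0))
  g <- graph[order(graph$source, graph$target, graph$type), , drop = FALSE]
  sprintf("<TLINK id=\"TL%d\" fromID=\"%s\" toID=\"%s\" type=\"%s\"/>",
          seq_len(nrow(g)) - 1L, xml_escape(g$source), xml_escape(g$target),
          g$type)
}

#' Write predicted relations as TLINK records
#'
#' Emits TLINK records (ordered by source id, then target id) in the dialect
#' read by [read_document()] / [read_predictions()]; reading the file back
#' yields the same relation set.
#'
#' @param graph A [relation_graph()].
#' @param path Output file path.
#' @param doc Optional document; when given, every relation endpoint must be
#'   a known mention id.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(graph, path, doc = NULL) {
  if (!is.null(doc)) {
    miss <- setdiff(unique(c(graph$source, graph$target)), doc$mentions$id)
    if (length(miss)) {
      stop("prediction references unknown mention id(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  lines <- c("<TemporalAnnotation>", "<TAGS>", tlink_lines(graph), "</TAGS>",
             "</TemporalAnnotation>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read TLINK records from a prediction or annotation file
#'
#' @param path File written by [write_predictions()] or
#'   [write_annotations()].
#' @param label_map TLINK label map.
#' @return A [relation_graph()].
#' @export
read_predictions <- function(path, label_map = default_tlink_label_map()) {
  xml <- xml2::read_xml(path)
  tlinks <- xml2::xml_find_all(xml, ".//TLINK")
  if (!length(tlinks)) return(relation_graph())
  relation_graph(xml2::xml_attr(tlinks, "fromID"),
                 xml2::xml_attr(tlinks, "toID"),
                 map_tlink_labels(xml2::xml_attr(tlinks, "type"), label_map))
}
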