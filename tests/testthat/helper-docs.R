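# In-code builders for small single- and multi-sentence test documents.

toy_frame <- function(pred, ...) {
  rows <- list(...)
  list(pred = as.integer(pred),
       args = data.frame(
         role = vapply(rows, `[[`, character(1), 1),
         from = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
         to = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
         kind = vapply(rows, function(r) {
           if (length(r) >= 4) r[[4]] else "ARGUMENT"
         }, character(1)),
         stringsAsFactors = FALSE))
}

# One-sentence document from a bracketed tree; mentions given as
# list(id, from, to, type) with category inferred from the leading letter of
# the id ("T" = time, "E" = event).
toy_doc <- function(doc_id, tree_str, mentions, frames = list(),
                    offset = 0L) {
  tree <- parse_bracketed_tree(tree_str)
  words <- tree_leaves(tree, "token")
  pos <- tree_leaves(tree, "label")
  starts <- offset + c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
  tokens <- data.frame(text = words, start = starts,
                       end = starts + nchar(words), pos = pos,
                       stringsAsFactors = FALSE)
  text <- paste(c(strrep(" ", offset), paste(words, collapse = " ")),
                collapse = "")
  sent <- annotated_sentence(offset, offset + sum(nchar(words)) +
                               length(words) - 1L, tokens, tree,
                             derive_dependencies(tree), frames)
  ms <- empty_toy_mentions()
  for (m in mentions) {
    row <- if (startsWith(m$id, "T")) {
      time_mention(m$id, tokens$start[m$from], tokens$end[m$to],
                   paste(words[m$from:m$to], collapse = " "), m$type)
    } else {
      event_mention(m$id, tokens$start[m$from], tokens$end[m$to],
                    paste(words[m$from:m$to], collapse = " "), m$type)
    }
    ms <- rbind(ms, row)
  }
  new_document(doc_id, text, list(sent), ms)
}

empty_toy_mentions <- function() {
  time_mention("Tx", 0, 1, "x", "DATE")[0, ]
}

# Multi-sentence document without trees: one sentence per line, mentions
# placed by token position. Enough for enumeration/closure/filter tests.
flat_doc <- function(doc_id, sentences, mentions, relations = NULL) {
  lines <- vapply(sentences, paste, character(1), collapse = " ")
  text <- paste(lines, collapse = "\n")
  starts <- cumsum(c(0L, nchar(lines) + 1L))[seq_along(lines)]
  sents <- lapply(seq_along(sentences), function(i) {
    words <- sentences[[i]]
    ws <- starts[i] + c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
    annotated_sentence(starts[i], starts[i] + nchar(lines[i]),
                       data.frame(text = words, start = ws,
                                  end = ws + nchar(words),
                                  pos = NA_character_,
                                  stringsAsFactors = FALSE))
  })
  ms <- empty_toy_mentions()
  for (m in mentions) {
    words <- sentences[[m$sent]]
    ws <- starts[m$sent] + c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
    txt <- paste(words[m$from:m$to], collapse = " ")
    row <- if (m$category == "TIME") {
      time_mention(m$id, ws[m$from], ws[m$to] + nchar(words[m$to]), txt,
                   m$type)
    } else {
      event_mention(m$id, ws[m$from], ws[m$to] + nchar(words[m$to]), txt,
                    m$type)
    }
    ms <- rbind(ms, row)
  }
  new_document(doc_id, text, sents, ms, relations)
}
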