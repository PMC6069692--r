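# Sidecar sentence-analysis format: one JSON record per line, one line per
# sentence (schema version 1). Linguistic analyses are inputs to this
# package, not computed by it; any tokenizer/parser/semantic-role labeler can
# populate the sidecar.
#
# Record fields:
#   start, end   sentence character span (0-based, half-open)
#   tokens       array of [text, start, end, pos]
#   tree         bracketed constituency parse, or null
#   deps         array of [head, dep, label] (1-based token indices, head 0
#                is the root)
#   frames       array of {pred, args: [{role, from, to, kind}]}
#   section      section label or null
#   enum_start   sentence starts with an enumeration mark
#   colon_end    sentence ends with a colon

SIDECAR_VERSION <- 1L

#' Write sidecar sentence analyses
#'
#' @param doc A [new_document()] whose sentences are populated.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(doc, path) {
  lines <- vapply(doc$sentences, function(s) {
    rec <- list(
      v = SIDECAR_VERSION,
      start = s$start, end = s$end,
      tokens = unname(apply(s$tokens, 1, function(r) {
        list(r[["text"]], as.integer(r[["start"]]), as.integer(r[["end"]]),
             r[["pos"]])
      })),
      tree = if (is.null(s$tree)) NULL else format_bracketed_tree(s$tree),
      deps = if (nrow(s$deps)) {
        unname(lapply(seq_len(nrow(s$deps)), function(i) {
          list(s$deps$head[i], s$deps$dep[i], s$deps$label[i])
        }))
      } else {
        list()
      },
      frames = lapply(s$frames, function(f) {
        list(pred = f$pred,
             args = lapply(seq_len(nrow(f$args)), function(i) {
               list(role = f$args$role[i], from = f$args$from[i],
                    to = f$args$to[i], kind = f$args$kind[i])
             }))
      }),
      section = if (is.na(s$section_label)) NULL else s$section_label,
      enum_start = s$starts_with_enumeration,
      colon_end = s$ends_with_colon
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read sidecar sentence analyses
#'
#' @param path A file written by [write_sidecar()] (or any producer of the
#'   documented schema).
#' @return List of [annotated_sentence()] records.
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    toks <- rec$tokens
    tokens <- data.frame(
      text = vapply(toks, function(t) as.character(t[[1]]), character(1)),
      start = vapply(toks, function(t) as.integer(t[[2]]), integer(1)),
      end = vapply(toks, function(t) as.integer(t[[3]]), integer(1)),
      pos = vapply(toks, function(t) {
        if (is.null(t[[4]])) NA_character_ else as.character(t[[4]])
      }, character(1)),
      stringsAsFactors = FALSE)
    deps <- if (length(rec$deps)) {
      data.frame(
        head = vapply(rec$deps, function(d) as.integer(d[[1]]), integer(1)),
        dep = vapply(rec$deps, function(d) as.integer(d[[2]]), integer(1)),
        label = vapply(rec$deps, function(d) as.character(d[[3]]),
                       character(1)),
        stringsAsFactors = FALSE)
    } else {
      NULL
    }
    frames <- lapply(rec$frames, function(f) {
      args <- f$args
      list(pred = as.integer(f$pred),
           args = data.frame(
             role = vapply(args, function(a) as.character(a$role),
                           character(1)),
             from = vapply(args, function(a) as.integer(a$from), integer(1)),
             to = vapply(args, function(a) as.integer(a$to), integer(1)),
             kind = vapply(args, function(a) as.character(a$kind),
                           character(1)),
             stringsAsFactors = FALSE))
    })
    annotated_sentence(
      start = rec$start, end = rec$end, tokens = tokens,
      tree = if (is.null(rec$tree)) NULL else
        parse_bracketed_tree(rec$tree),
      deps = deps, frames = frames,
      section_label = if (is.null(rec$section)) NA_character_ else
        rec$section,
      starts_with_enumeration = isTRUE(rec$enum_start),
      ends_with_colon = isTRUE(rec$colon_end))
  })
}
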