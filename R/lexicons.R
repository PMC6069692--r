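# Plain-text configuration lexicons: type-preserving phrase templates,
# medication-frequency terms, and section headers. One entry per line,
# "#" starts a comment.

read_lexicon_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Load a type-preserving phrase lexicon
#'
#' A type-preserving phrase is a phrase whose head is not the time/event
#' mention but whose overall semantic type still counts as that mention
#' (e.g. "an episode of diarrhea" still denotes the problem "diarrhea").
#' Each template contains exactly one bracketed placeholder naming the
#' mention class it preserves, e.g. `episodes of [Event-Problem]`.
#'
#' @param path Path to a template file; the default is the lexicon shipped
#'   with the package.
#' @return Data frame of class `tp_lexicon` with columns `template`, `class`,
#'   and list-columns `pre`/`post` of lowercased tokens surrounding the
#'   placeholder.
#' @export
type_preserving_lexicon <- function(path = system.file("extdata",
                                                       "type_preserving_phrases.txt",
                                                       package = "dirtlink")) {
  lines <- read_lexicon_lines(path)
  parse_tp_templates(lines)
}

#' Build a type-preserving lexicon from template strings
#'
#' @param templates Character vector of templates, each with one
#'   `[Class]` placeholder (classes: `Event-Problem`, `Event-Treatment`,
#'   `Event-Test`, `Time-Date`, `Time-Duration`, `Time-Time`,
#'   `Time-Frequency`).
#' @return A `tp_lexicon` data frame; an empty vector yields an empty lexicon
#'   (disabling the type-preserving exception).
#' @export
parse_tp_templates <- function(templates) {
  classes <- c("Event-Problem", "Event-Treatment", "Event-Test",
               "Time-Date", "Time-Duration", "Time-Time", "Time-Frequency")
  out <- data.frame(template = character(), class = character(),
                    stringsAsFactors = FALSE)
  pre <- list()
  post <- list()
  for (tmpl in templates) {
    toks <- strsplit(trimws(tmpl), "[[:space:]]+")[[1]]
    ph <- grep("^\\[.*\\]$", toks)
    if (length(ph) != 1) {
      stop("template must contain exactly one [Class] placeholder: '",
           tmpl, "'", call. = FALSE)
    }
    cls <- sub("^\\[(.*)\\]$", "\\1", toks[ph])
    if (!cls %in% classes) {
      stop("unknown placeholder class '", cls, "' in template '", tmpl, "'",
           call. = FALSE)
    }
    out <- rbind(out, data.frame(template = tmpl, class = cls,
                                 stringsAsFactors = FALSE))
    pre[[length(pre) + 1L]] <- tolower(toks[seq_len(ph - 1L)])
    post[[length(post) + 1L]] <- if (ph < length(toks)) {
      tolower(toks[(ph + 1L):length(toks)])
    } else {
      character(0)
    }
  }
  out$pre <- pre
  out$post <- post
  class(out) <- c("tp_lexicon", "data.frame")
  out
}

# Does the mention's category/attributes satisfy a placeholder class?
mention_matches_class <- function(mention, class) {
  part <- strsplit(class, "-", fixed = TRUE)[[1]]
  if (part[1] == "Event") {
    mention$category == "EVENT" &&
      identical(mention$event_type, toupper(part[2]))
  } else {
    mention$category == "TIME" &&
      identical(mention$time_type, toupper(part[2]))
  }
}

#' Load the medication-frequency lexicon
#'
#' Time expressions of type FREQUENCY whose surface form is in this lexicon
#' (e.g. "bid", "prn", "q2h") denote medication dosing schedules; predicted
#' relations pairing them with problem-type events are removed in
#' post-processing.
#'
#' @param path Path to the lexicon file; defaults to the shipped list.
#' @return Lowercased character vector of frequency terms.
#' @export
medication_frequency_lexicon <- function(path = system.file("extdata",
                                                            "medication_frequencies.txt",
                                                            package = "dirtlink")) {
  tolower(read_lexicon_lines(path))
}

#' Load the section-header lexicon
#'
#' @param path Path to a file of section header names (without trailing
#'   colon); defaults to the shipped list.
#' @return Character vector of header names.
#' @export
section_header_lexicon <- function(path = system.file("extdata",
                                                      "section_headers.txt",
                                                      package = "dirtlink")) {
  read_lexicon_lines(path)
}

#' Detect document sections from header lines
#'
#' A line consisting of a known header (case-insensitive) followed by a colon
#' opens a section that extends to the next header or the end of the text.
#'
#' @param text Raw document text.
#' @param lexicon Header names ([section_header_lexicon()]).
#' @return Data frame with columns `start`, `end` (0-based half-open char
#'   spans) and `label`; positions before the first header get label `NA`.
#' @export
detect_sections <- function(text, lexicon = section_header_lexicon()) {
  lines <- strsplit(paste0(text, "\n"), "\n", fixed = TRUE)[[1]]
  starts <- cumsum(c(0L, nchar(lines) + 1L))[seq_along(lines)]
  is_header <- function(line) {
    line <- trimws(line)
    if (!grepl(":$", line)) return(NA_character_)
    name <- sub(":.*$", "", line)
    hit <- match(toupper(name), toupper(lexicon))
    if (is.na(hit)) NA_character_ else lexicon[hit]
  }
  labels <- vapply(lines, is_header, character(1), USE.NAMES = FALSE)
  out <- data.frame(start = integer(), end = integer(), label = character(),
                    stringsAsFactors = FALSE)
  cur_label <- NA_character_
  cur_start <- 0L
  for (i in seq_along(lines)) {
    if (!is.na(labels[i])) {
      if (starts[i] > cur_start) {
        out <- rbind(out, data.frame(start = cur_start, end = starts[i],
                                     label = cur_label,
                                     stringsAsFactors = FALSE))
      }
      cur_label <- labels[i]
      cur_start <- starts[i]
    }
  }
  out <- rbind(out, data.frame(start = cur_start, end = nchar(text),
                               label = cur_label, stringsAsFactors = FALSE))
  out
}

section_for_position <- function(sections, pos) {
  hit <- which(sections$start <= pos & pos < sections$end)
  if (length(hit)) sections$label[hit[1]] else NA_character_
}
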