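# Head finding over constituency trees.
#
# The head of a phrase is the sub-phrase that determines its syntactic type
# (the noun of an NP, the preposition of a PP, ...). Head children are found
# with per-label scan rules in the style of classic head-percolation tables:
# scan the children in a fixed direction and take the first whose label is in
# the rule's label set; if none matches, take the first child in the scan
# direction. Labels without a rule fall back to the leftmost child.

#' Default head-finding table
#'
#' @return A named list mapping constituent labels to
#'   `list(dir = "left"|"right", set = <label character vector>)`.
#' @export
default_head_table <- function() {
  list(
    NP    = list(dir = "right", set = c("NN", "NNS", "NNP", "NNPS", "NX",
                                        "NML", "NP", "PRP", "CD", "QP",
                                        "JJ", "JJR", "JJS")),
    NX    = list(dir = "right", set = c("NN", "NNS", "NNP", "NNPS", "NX")),
    NML   = list(dir = "right", set = c("NN", "NNS", "NNP", "NNPS", "NML")),
    WHNP  = list(dir = "right", set = c("NN", "NNS", "NNP", "WP", "WDT", "NP")),
    PP    = list(dir = "left",  set = c("IN", "TO", "RP")),
    WHPP  = list(dir = "left",  set = c("IN", "TO")),
    VP    = list(dir = "left",  set = c("VBD", "VBN", "MD", "VBZ", "VB",
                                        "VBG", "VBP", "VP")),
    ADVP  = list(dir = "right", set = c("RB", "RBR", "RBS", "ADVP", "NP", "IN")),
    ADJP  = list(dir = "right", set = c("JJ", "JJR", "JJS", "ADJP", "VBN", "RB")),
    QP    = list(dir = "right", set = c("CD", "NN", "JJ")),
    S     = list(dir = "left",  set = c("VP", "S", "SBAR")),
    SINV  = list(dir = "left",  set = c("VP", "S", "SBAR")),
    SQ    = list(dir = "left",  set = c("VP", "MD", "VBZ", "VBD", "VBP")),
    SBAR  = list(dir = "left",  set = c("S", "IN", "WHNP", "WHADVP"))
  )
}

#' Find the head child of a constituent
#'
#' @param node A non-terminal `const_node`.
#' @param table A head table ([default_head_table()]).
#' @return The index of the head child within `node$children`.
#' @export
find_head <- function(node, table = default_head_table()) {
  stopifnot(!node$terminal)
  k <- length(node$children)
  labs <- vapply(node$children, function(ch) ch$label, character(1))
  # a coordinated phrase is headed by its leftmost conjunct
  if (is_coordinated(node, node$label)) {
    return(which(labs == node$label)[1L])
  }
  rule <- table[[node$label]]
  if (is.null(rule)) return(1L)
  order <- if (rule$dir == "right") rev(seq_len(k)) else seq_len(k)
  for (i in order) {
    if (labs[i] %in% rule$set) return(i)
  }
  order[1L]
}

#' Lexical head token of a constituent
#'
#' Recursively follows head children down to a terminal.
#'
#' @inheritParams find_head
#' @return The 1-based token index of the lexical head.
#' @export
lexical_head_index <- function(node, table = default_head_table()) {
  while (!node$terminal) {
    node <- node$children[[find_head(node, table)]]
  }
  node$from
}
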