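# Penn-Treebank-style bracketed constituency trees.
#
# A tree node is a list with fields:
#   label    constituent or POS label
#   terminal TRUE for leaves
#   token    surface token (terminals only)
#   children list of child nodes (non-terminals only)
#   from, to 1-based inclusive token span, assigned by index_tree()

const_node <- function(label, children) {
  structure(list(label = label, terminal = FALSE, token = NULL,
                 children = children, from = NA_integer_, to = NA_integer_),
            class = "const_node")
}

const_leaf <- function(label, token) {
  structure(list(label = label, terminal = TRUE, token = token,
                 children = list(), from = NA_integer_, to = NA_integer_),
            class = "const_node")
}

#' Parse a bracketed constituency tree
#'
#' Reads Penn-Treebank-style bracketing such as
#' `"(NP (JJ laparoscopic) (NN cholecystectomy))"`. Leaf spans (1-based,
#' inclusive token indices) are assigned on the way out, so the result is
#' ready for head finding. Parsing and printing round-trip modulo whitespace.
#'
#' @param text A single bracketed string with balanced parentheses.
#' @return A tree node of class `const_node`.
#' @export
parse_bracketed_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)
  skip_ws <- function() {
    while (pos <= n && grepl("^[[:space:]]$", chars[pos])) pos <<- pos + 1L
  }
  read_atom <- function() {
    start <- pos
    while (pos <= n && !chars[pos] %in% c("(", ")") &&
           !grepl("^[[:space:]]$", chars[pos])) {
      pos <<- pos + 1L
    }
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parse_node <- function() {
    skip_ws()
    if (pos > n || chars[pos] != "(") {
      stop("tree parse error at character ", pos,
           ": expected '('", call. = FALSE)
    }
    open_at <- pos
    pos <<- pos + 1L
    skip_ws()
    label <- if (pos <= n && !chars[pos] %in% c("(", ")")) read_atom() else ""
    skip_ws()
    if (pos > n) {
      stop("tree parse error at character ", open_at,
           ": unbalanced '('", call. = FALSE)
    }
    if (chars[pos] == "(") {
      children <- list()
      while (TRUE) {
        skip_ws()
        if (pos > n) {
          stop("tree parse error at character ", open_at,
               ": unbalanced '('", call. = FALSE)
        }
        if (chars[pos] == ")") { pos <<- pos + 1L; break }
        children[[length(children) + 1L]] <- parse_node()
      }
      if (!length(children)) {
        stop("tree parse error at character ", open_at,
             ": empty constituent", call. = FALSE)
      }
      # collapse a label-less wrapper with a single child (common root form)
      if (label == "" && length(children) == 1L) return(children[[1L]])
      const_node(label, children)
    } else if (chars[pos] == ")") {
      stop("tree parse error at character ", pos,
           ": constituent with no content", call. = FALSE)
    } else {
      token <- read_atom()
      skip_ws()
      if (pos > n || chars[pos] != ")") {
        stop("tree parse error at character ",
             min(pos, n), ": unbalanced '('", call. = FALSE)
      }
      pos <<- pos + 1L
      const_leaf(label, token)
    }
  }
  node <- parse_node()
  skip_ws()
  if (pos <= n) {
    stop("tree parse error at character ", pos,
         ": trailing content after tree", call. = FALSE)
  }
  index_tree(node)
}

#' Serialize a constituency tree to bracketed notation
#'
#' @param node A `const_node`.
#' @return A single bracketed string; `parse_bracketed_tree()` of the result
#'   reproduces the tree.
#' @export
format_bracketed_tree <- function(node) {
  if (node$terminal) {
    paste0("(", node$label, " ", node$token, ")")
  } else {
    paste0("(", node$label, " ",
           paste(vapply(node$children, format_bracketed_tree, character(1)),
                 collapse = " "),
           ")")
  }
}

# Assign from/to token spans bottom-up; leaves are numbered left to right.
index_tree <- function(node, start = 1L) {
  if (node$terminal) {
    node$from <- start
    node$to <- start
    return(node)
  }
  at <- start
  for (i in seq_along(node$children)) {
    node$children[[i]] <- index_tree(node$children[[i]], at)
    at <- node$children[[i]]$to + 1L
  }
  node$from <- start
  node$to <- at - 1L
  node
}

#' Extract leaf tokens of a tree
#'
#' @param node A `const_node`.
#' @param what `"token"` for surface strings, `"label"` for POS tags.
#' @return Character vector in leaf order.
#' @export
tree_leaves <- function(node, what = c("token", "label")) {
  what <- match.arg(what)
  if (node$terminal) {
    return(if (what == "token") node$token else node$label)
  }
  unlist(lapply(node$children, tree_leaves, what = what))
}

# Path from the root to the smallest node covering token range [from, to].
# Returns list(nodes = list of nodes root..smallest, idx = child indices
# taken at each step; length(idx) == length(nodes) - 1).
covering_path <- function(tree, from, to) {
  stopifnot(from >= tree$from, to <= tree$to, from <= to)
  nodes <- list(tree)
  idx <- integer(0)
  node <- tree
  repeat {
    if (node$terminal) break
    child <- NULL
    ci <- NA_integer_
    for (i in seq_along(node$children)) {
      ch <- node$children[[i]]
      if (ch$from <= from && to <= ch$to) { child <- ch; ci <- i; break }
    }
    if (is.null(child)) break
    nodes[[length(nodes) + 1L]] <- child
    idx <- c(idx, ci)
    node <- child
  }
  list(nodes = nodes, idx = idx)
}

node_at_path <- function(tree, path) {
  node <- tree
  for (i in path) node <- node$children[[i]]
  node
}
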