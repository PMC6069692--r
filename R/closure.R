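# Temporal-relation algebra: inverses, composition, transitive closure,
# contradiction reporting, and the intra-sentential time-event filter used
# during corpus construction.
#
# The algebra works over the three relation types BEFORE / AFTER / OVERLAP.
# Only four compositions are licensed:
#   BEFORE  o BEFORE  = BEFORE
#   BEFORE  o OVERLAP = BEFORE
#   OVERLAP o BEFORE  = BEFORE
#   OVERLAP o OVERLAP = OVERLAP
# AFTER never needs dedicated entries: the closure is additionally closed
# under inversion, so AFTER chains follow from the BEFORE entries. All other
# compositions infer nothing (no Allen-style disjunctions are imported).

#' The minimal composition table
#'
#' @return A data frame with columns `first`, `second`, `result` listing the
#'   four licensed compositions.
#' @export
composition_table <- function() {
  data.frame(
    first  = c("BEFORE", "BEFORE", "OVERLAP", "OVERLAP"),
    second = c("BEFORE", "OVERLAP", "BEFORE", "OVERLAP"),
    result = c("BEFORE", "BEFORE", "BEFORE", "OVERLAP"),
    stringsAsFactors = FALSE
  )
}

#' Compose two relation types
#'
#' @param r1,r2 Relation types (`"BEFORE"`, `"AFTER"`, `"OVERLAP"`); if A
#'   `r1` B and B `r2` C, the result relates A to C.
#' @return The composed type, or `"NONE"` when the composition is not
#'   licensed.
#' @export
compose_types <- function(r1, r2) {
  tab <- composition_table()
  hit <- tab$result[tab$first == r1 & tab$second == r2]
  if (length(hit)) hit else "NONE"
}

#' Invert relations
#'
#' (A BEFORE B) becomes (B AFTER A), (A AFTER B) becomes (B BEFORE A), and
#' OVERLAP is symmetric. Inversion is an involution.
#'
#' @param graph A [relation_graph()] (or any data frame with `source`,
#'   `target`, `type`).
#' @return The inverted relation set.
#' @export
invert_relations <- function(graph) {
  inv <- invert_rows(graph)
  relation_graph(inv$source, inv$target, inv$type)
}

# Row-order-preserving inversion (no dedup/sort), for in-place reorientation.
invert_rows <- function(df) {
  inv <- c(BEFORE = "AFTER", AFTER = "BEFORE", OVERLAP = "OVERLAP")
  data.frame(source = df$target, target = df$source,
             type = unname(inv[df$type]), stringsAsFactors = FALSE)
}

# Internal boolean-matrix core shared by closure and contradiction search.
# Returns list(ids, B, O): B[i, j] TRUE iff i BEFORE j; O symmetric overlap.
closure_matrices <- function(graph) {
  ids <- sort(unique(c(graph$source, graph$target)))
  n <- length(ids)
  B <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  O <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  s <- match(graph$source, ids)
  t <- match(graph$target, ids)
  for (k in seq_len(nrow(graph))) {
    switch(graph$type[k],
           BEFORE = { B[s[k], t[k]] <- TRUE },
           AFTER = { B[t[k], s[k]] <- TRUE },
           OVERLAP = { O[s[k], t[k]] <- TRUE; O[t[k], s[k]] <- TRUE })
  }
  repeat {
    O2 <- O | t(O) | ((O %*% O) > 0)
    B2 <- B | ((B %*% B) > 0) | ((B %*% O2) > 0) | ((O2 %*% B) > 0)
    diag(O2) <- FALSE
    diag(B2) <- FALSE
    if (identical(B2, B) && identical(O2, O)) break
    B <- B2
    O <- O2
  }
  list(ids = ids, B = B, O = O)
}

matrices_to_graph <- function(m) {
  before <- which(m$B, arr.ind = TRUE)
  overlap <- which(m$O, arr.ind = TRUE)
  # entries are unique and valid by construction; skip revalidation
  g <- data.frame(
    source = c(m$ids[before[, 1]], m$ids[before[, 2]], m$ids[overlap[, 1]]),
    target = c(m$ids[before[, 2]], m$ids[before[, 1]], m$ids[overlap[, 2]]),
    type = c(rep("BEFORE", nrow(before)), rep("AFTER", nrow(before)),
             rep("OVERLAP", nrow(overlap))),
    stringsAsFactors = FALSE)
  g <- g[order(g$source, g$target, g$type), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("relation_graph", "data.frame")
  g
}

#' Transitive closure of a relation set
#'
#' Computes the smallest superset of the input closed under inversion and the
#' four licensed compositions (a fixed point: applying the rules again adds
#' nothing). Contradictions that arise (a pair carrying two distinct types)
#' are retained in the output; use [find_contradictions()] to surface them.
#'
#' @param graph A [relation_graph()].
#' @return The closed [relation_graph()], a superset of the input.
#' @export
transitive_closure <- function(graph) {
  if (!nrow(graph)) return(relation_graph())
  matrices_to_graph(closure_matrices(graph))
}

#' Report contradictory relation pairs
#'
#' Closes the graph, then reports every mention pair that carries two or more
#' distinct relation types (after canonical reorientation, so a consistent
#' BEFORE/AFTER mirror pair is not a contradiction). Closure over seed
#' annotations can produce such conflicts; they are reported for review, not
#' resolved automatically.
#'
#' @param graph A [relation_graph()].
#' @return Data frame with columns `a`, `b`, `types` (comma-joined conflicting
#'   types on the pair oriented a -> b, `a < b`); one row per unordered pair.
#' @export
find_contradictions <- function(graph) {
  empty <- data.frame(a = character(), b = character(), types = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(graph)) return(empty)
  g <- transitive_closure(graph)
  flip <- g$source > g$target
  canon <- as.data.frame(g)
  canon[flip, c("source", "target", "type")] <-
    invert_rows(g[flip, , drop = FALSE])
  key <- paste(canon$source, canon$target, sep = "\r")
  out <- empty
  for (k in unique(key)) {
    types <- sort(unique(canon$type[key == k]))
    if (length(types) >= 2) {
      pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
      out <- rbind(out, data.frame(a = pr[1], b = pr[2],
                                   types = paste(types, collapse = ","),
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$a, out$b), , drop = FALSE]
}

#' Keep intra-sentential time-event relations, canonically oriented
#'
#' Implements the corpus-construction filter: only relations with one time
#' expression and one event mention in the same sentence survive; each is
#' reoriented (by inversion if needed) so the time expression is the source.
#'
#' @param graph A [relation_graph()].
#' @param doc The [new_document()] whose mentions the graph references.
#' @return The filtered, canonicalized [relation_graph()].
#' @export
filter_intra_sentential_time_event <- function(graph, doc) {
  if (!nrow(graph)) return(relation_graph())
  m <- doc$mentions
  miss <- setdiff(unique(c(graph$source, graph$target)), m$id)
  if (length(miss)) {
    stop("relation references unknown mention id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  si <- match(graph$source, m$id)
  ti <- match(graph$target, m$id)
  cats <- paste(m$category[si], m$category[ti])
  keep <- (cats %in% c("TIME EVENT", "EVENT TIME")) &
    m$sentence_index[si] == m$sentence_index[ti]
  g <- graph[keep, , drop = FALSE]
  if (!nrow(g)) return(relation_graph())
  flip <- m$category[match(g$source, m$id)] == "EVENT"
  g <- as.data.frame(g)
  g[flip, c("source", "target", "type")] <- invert_rows(g[flip, , drop = FALSE])
  as_relation_graph(g)
}
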