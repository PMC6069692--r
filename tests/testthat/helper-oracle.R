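# Independent naive fixed-point oracle for the closure algebra: stores
# relations in a mention x mention x type logical array and literally applies
# the inversion and composition rules one relation at a time until nothing
# changes. Deliberately shares no code with the package's matrix-product
# closure.

ORACLE_TYPES <- c("BEFORE", "AFTER", "OVERLAP")

oracle_closure <- function(src, tgt, typ, ids) {
  n <- length(ids)
  R <- array(FALSE, c(n, n, 3))
  for (k in seq_along(src)) {
    R[match(src[k], ids), match(tgt[k], ids), match(typ[k], ORACLE_TYPES)] <-
      TRUE
  }
  inv <- c(2L, 1L, 3L)
  comp <- matrix(NA_integer_, 3, 3)
  comp[1, 1] <- 1L  # before  o before  = before
  comp[1, 3] <- 1L  # before  o overlap = before
  comp[3, 1] <- 1L  # overlap o before  = before
  comp[3, 3] <- 3L  # overlap o overlap = overlap
  repeat {
    changed <- FALSE
    idx <- which(R, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; t1 <- idx[r, 3]
      if (!R[j, i, inv[t1]]) {
        R[j, i, inv[t1]] <- TRUE
        changed <- TRUE
      }
      for (s in seq_len(nrow(idx))) {
        if (idx[s, 1] == j) {
          k <- idx[s, 2]; t2 <- idx[s, 3]
          if (k != i && !is.na(comp[t1, t2]) && !R[i, k, comp[t1, t2]]) {
            R[i, k, comp[t1, t2]] <- TRUE
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  R
}

graph_to_array <- function(g, ids) {
  n <- length(ids)
  R <- array(FALSE, c(n, n, 3))
  for (k in seq_len(nrow(g))) {
    R[match(g$source[k], ids), match(g$target[k], ids),
      match(g$type[k], ORACLE_TYPES)] <- TRUE
  }
  R
}

graph_key <- function(g) sort(paste(g$source, g$target, g$type, sep = "|"))

random_graph <- function(n_mentions, n_seeds) {
  ids <- letters[seq_len(n_mentions)]
  src <- sample(ids, n_seeds, replace = TRUE)
  tgt <- sample(ids, n_seeds, replace = TRUE)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  if (!length(src)) {
    src <- ids[1]; tgt <- ids[2]
  }
  typ <- sample(ORACLE_TYPES, length(src), replace = TRUE)
  list(ids = ids, graph = relation_graph(src, tgt, typ),
       src = src, tgt = tgt, typ = typ)
}
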