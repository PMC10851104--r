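# Independent brute-force oracles used to check the package's optimized
# implementations. These deliberately share no code with the package paths
# they validate.

# All-pairs inter-chain residue contacts with min distances: full distance
# matrix, heavy atoms only, inclusive cutoff.
oracle_contacts <- function(structure, cutoff = 5.0) {
  at <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  n <- nrow(at)
  if (n < 2) {
    return(data.frame(key = character(0), min_distance = numeric(0)))
  }
  dm <- as.matrix(stats::dist(cbind(at$x, at$y, at$z)))
  res <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (at$chain_id[i] == at$chain_id[j]) next
      if (dm[i, j] > cutoff) next
      a <- c(at$chain_id[i], at$residue_seq_id[i])
      b <- c(at$chain_id[j], at$residue_seq_id[j])
      if (a[1] > b[1] || (a[1] == b[1] &&
                          as.integer(a[2]) > as.integer(b[2]))) {
        tmp <- a; a <- b; b <- tmp
      }
      key <- paste(a[1], a[2], b[1], b[2])
      d <- dm[i, j]
      if (is.null(res[[key]]) || d < res[[key]]) res[[key]] <- d
    }
  }
  if (!length(res)) {
    return(data.frame(key = character(0), min_distance = numeric(0)))
  }
  data.frame(key = names(res), min_distance = unlist(res),
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorized variant for larger structures (still independent of the grid):
# chunked distance computation over the full cross product
oracle_contacts_fast <- function(structure, cutoff = 5.0) {
  at <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  n <- nrow(at)
  if (n < 2) {
    return(data.frame(key = character(0), min_distance = numeric(0)))
  }
  dm <- as.matrix(stats::dist(cbind(at$x, at$y, at$z)))
  hit <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(key = character(0), min_distance = numeric(0)))
  }
  i <- hit[, 1]; j <- hit[, 2]
  keep <- at$chain_id[i] != at$chain_id[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) {
    return(data.frame(key = character(0), min_distance = numeric(0)))
  }
  d <- dm[cbind(i, j)]
  swap <- (at$chain_id[i] > at$chain_id[j]) |
    (at$chain_id[i] == at$chain_id[j] &
       at$residue_seq_id[i] > at$residue_seq_id[j])
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(at$chain_id[i], at$residue_seq_id[i],
               at$chain_id[j], at$residue_seq_id[j])
  md <- tapply(d, key, min)
  data.frame(key = names(md), min_distance = as.numeric(md),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Exhaustive maximal-clique enumeration over all vertex subsets (n <= 15).
oracle_cliques <- function(edge_df, all_nodes = NULL) {
  nodes <- sort(unique(c(edge_df[[1]], edge_df[[2]], all_nodes)))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edge_df))) {
    A[edge_df[[1]][r], edge_df[[2]][r]] <- TRUE
    A[edge_df[[2]][r], edge_df[[1]][r]] <- TRUE
  }
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(A[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
  }
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx) || !is_clique(idx)) next
    outside <- setdiff(seq_len(n), idx)
    maximal <- !any(vapply(outside, function(v) all(A[v, idx]), logical(1)))
    if (maximal) cliques[[length(cliques) + 1]] <- nodes[idx]
  }
  cliques
}

# Direct evaluation of MCC from a clique list.
oracle_mcc <- function(cliques, node) {
  sum(vapply(cliques, function(cl)
    if (node %in% cl) factorial(length(cl) - 1) else 0, numeric(1)))
}

clique_fingerprint <- function(cliques) {
  sort(vapply(cliques, function(cl) paste(sort(cl), collapse = ","),
              character(1)))
}
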