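# Topological analysis: maximal cliques, Maximal Clique Centrality, local
# clustering, topological coefficient, betweenness, hub calling and the
# coefficient-vs-degree decay check.
#
# Clique enumeration is a Bron-Kerbosch recursion with pivoting; Maximal
# Clique Centrality is MCC(v) = sum over maximal cliques C containing v of
# (|C|-1)!. An isolated node owns its singleton maximal clique, so its MCC is
# 0! = 1.

# Accept a hinet, an igraph object, or a two-column edge data.frame.
.as_graph <- function(x) {
  if (inherits(x, "hinet")) return(as_igraph(x))
  if (inherits(x, "igraph")) return(x)
  if (is.data.frame(x)) {
    g <- igraph::graph_from_data_frame(x[, 1:2], directed = FALSE)
    return(igraph::simplify(g))
  }
  stop("cannot interpret input as a graph")
}

.adjacency_list <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), function(v)
    sort(unique(as.integer(v))))
  # guard against self-loops
  lapply(seq_len(n), function(i) setdiff(adj[[i]], i))
}

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch with pivot selection. Every maximal clique is returned
#' exactly once; isolated nodes yield singleton cliques.
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @return list of character vectors of node names (sorted within cliques).
#' @export
enumerate_maximal_cliques <- function(x) {
  g <- .as_graph(x)
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  adj <- .adjacency_list(g)
  out <- new.env(parent = emptyenv())
  out$cl <- list()
  out$k <- 0L
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out$k <- out$k + 1L
      out$cl[[out$k]] <- R
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbors in P
    cand <- c(P, X)
    deg_in_p <- vapply(cand, function(u) length(intersect(adj[[u]], P)),
                       integer(1))
    pivot <- cand[which.max(deg_in_p)]
    for (v in setdiff(P, adj[[pivot]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }
  bk(integer(0), seq_len(n), integer(0))
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  lapply(out$cl, function(idx) sort(nm[idx]))
}

#' Maximal Clique Centrality
#'
#' MCC(v) = sum over maximal cliques C containing v of (|C|-1)!. The formula
#' is applied literally; an isolated node scores 0! = 1 via its singleton
#' maximal clique.
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @param node optional single node name; default scores all nodes.
#' @param cliques optional precomputed clique list from
#'   [enumerate_maximal_cliques()].
#' @return named numeric vector of integer-valued scores (or a single value
#'   when `node` is given).
#' @export
mcc_score <- function(x, node = NULL, cliques = NULL) {
  g <- .as_graph(x)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  if (is.null(cliques)) cliques <- enumerate_maximal_cliques(g)
  scores <- stats::setNames(numeric(length(nm)), nm)
  for (cl in cliques) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  if (!is.null(node)) {
    if (!node %in% nm) stop("node '", node, "' absent from network")
    return(scores[[node]])
  }
  scores
}

#' Local clustering coefficient
#'
#' C(v) = 2 e_N / (k (k - 1)) where e_N counts edges among the neighbors of
#' v; defined as 0 for nodes of degree < 2.
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @param node optional single node name.
#' @return named numeric vector (or single value).
#' @export
clustering_coefficient <- function(x, node = NULL) {
  g <- .as_graph(x)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  names(cc) <- nm
  if (!is.null(node)) return(cc[[node]])
  cc
}

#' Topological coefficient
#'
#' T(v) = mean over nodes m != v sharing at least one neighbor with v of
#' J(v, m), divided by k(v), where J(v, m) is the number of shared neighbors
#' plus 1 if v and m are adjacent (NetworkAnalyzer convention). Nodes with no
#' co-neighbors (or degree 0) report 0 and are flagged via the `undefined`
#' attribute.
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @param node optional single node name.
#' @return named numeric vector with attribute `undefined` (logical vector).
#' @export
topological_coefficient <- function(x, node = NULL) {
  g <- .as_graph(x)
  n <- igraph::vcount(g)
  adj <- .adjacency_list(g)
  deg <- lengths(adj)
  tc <- numeric(n)
  undef <- logical(n)
  for (v in seq_len(n)) {
    if (deg[v] == 0) { undef[v] <- TRUE; next }
    # candidate partners: nodes at distance <= 2 sharing a neighbor
    cand <- unique(unlist(adj[adj[[v]]]))
    cand <- union(cand, adj[[v]])
    cand <- setdiff(cand, v)
    J <- vapply(cand, function(m) {
      s <- length(intersect(adj[[v]], adj[[m]]))
      if (s == 0 && !(m %in% adj[[v]])) return(NA_real_)
      if (s == 0) return(NA_real_)  # adjacency alone does not qualify
      s + as.numeric(m %in% adj[[v]])
    }, numeric(1))
    J <- J[!is.na(J)]
    if (!length(J)) { undef[v] <- TRUE; next }
    tc[v] <- mean(J) / deg[v]
  }
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  names(tc) <- nm
  names(undef) <- nm
  attr(tc, "undefined") <- undef
  if (!is.null(node)) {
    out <- tc[[node]]
    attr(out, "undefined") <- undef[[node]]
    return(out)
  }
  tc
}

#' Normalized betweenness centrality
#'
#' Brandes shortest-path betweenness on the unweighted graph, normalized by
#' (N-1)(N-2)/2 for undirected graphs.
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(x) {
  g <- .as_graph(x)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  stats::setNames(as.numeric(b), nm)
}

#' Identify hub nodes by Maximal Clique Centrality
#'
#' Either every node with MCC at or above a threshold, or the `top_n` nodes
#' ranked by MCC (ties broken lexicographically by node id).
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @param mcc_threshold integer threshold (default 4).
#' @param top_n optional fixed hub count; overrides the threshold mode.
#' @return character vector of hub node ids.
#' @export
identify_hubs <- function(x, mcc_threshold = 4, top_n = NULL) {
  scores <- mcc_score(x)
  if (!length(scores)) return(character(0))
  if (!is.null(top_n)) {
    ord <- order(-scores, names(scores))
    return(names(scores)[ord][seq_len(min(top_n, length(scores)))])
  }
  sort(names(scores)[scores >= mcc_threshold])
}

#' Full per-node topology report
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @param mcc_threshold hub threshold passed to [identify_hubs()].
#' @return data.frame: node_id, degree, clustering, topological, betweenness,
#'   mcc, is_hub.
#' @export
topology_report <- function(x, mcc_threshold = 4) {
  g <- .as_graph(x)
  cliques <- enumerate_maximal_cliques(g)
  mcc <- mcc_score(g, cliques = cliques)
  tc <- topological_coefficient(g)
  out <- data.frame(
    node_id = names(mcc),
    degree = as.integer(igraph::degree(g)),
    clustering = as.numeric(clustering_coefficient(g)),
    topological = as.numeric(tc),
    betweenness = as.numeric(betweenness_centrality(g)),
    mcc = as.numeric(mcc),
    stringsAsFactors = FALSE
  )
  out$is_hub <- out$mcc >= mcc_threshold
  rownames(out) <- NULL
  out
}

#' Write a topology report to TSV
#' @param report data.frame from [topology_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check power-law-like decay of a coefficient with degree
#'
#' Regresses the per-degree mean of the chosen coefficient on degree in
#' log-log space (degrees with positive mean only, since zeros have no
#' log-scale representation) and reports the regression slope together with
#' the Spearman correlation between degree and the per-node coefficient,
#' computed over nodes with a positive coefficient -- the nodes that appear
#' on a log-scale decay plot. A scale-free-like network shows a negative
#' slope and a negative correlation.
#'
#' @param x a `hinet`, igraph object or edge data.frame.
#' @param metric "clustering" or "topological".
#' @param min_degrees minimum number of distinct degrees required.
#' @return list with `slope` and `spearman_rho`.
#' @export
powerlaw_decay_check <- function(x, metric = c("clustering", "topological"),
                                 min_degrees = 10) {
  metric <- match.arg(metric)
  g <- .as_graph(x)
  k <- as.numeric(igraph::degree(g))
  if (length(unique(k)) < min_degrees) {
    stop("degenerate degree distribution: ", length(unique(k)),
         " distinct degrees (need >= ", min_degrees, ")")
  }
  v <- if (metric == "clustering") as.numeric(clustering_coefficient(g))
       else as.numeric(topological_coefficient(g))
  mean_v <- tapply(v, k, mean)
  kk <- as.numeric(names(mean_v))
  pos <- mean_v > 0 & kk > 0
  if (sum(pos) < 3) stop("too few degrees with positive mean coefficient")
  fit <- stats::lm(log10(mean_v[pos]) ~ log10(kk[pos]))
  sel <- v > 0
  rho <- stats::cor(k[sel], v[sel], method = "spearman")
  list(slope = unname(stats::coef(fit)[2]), spearman_rho = rho)
}
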