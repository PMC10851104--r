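# Interaction networks at residue, domain and protein granularity.
#
# A network ("hinet") is a simple undirected annotated graph: a node table
# (node_id, node_class, histone_type, organism) and an edge table with a
# per-edge evidence set (structure ids, crosslink, highthroughput). Edges are
# stored canonically (node_a < node_b) and never self-looped.

#' Construct a network object
#'
#' @param nodes data.frame with at least node_id and node_class.
#' @param edges data.frame with node_a, node_b, optional interaction_class
#'   and evidence (list column of character vectors).
#' @param granularity one of "residue", "domain", "protein".
#' @param provenance label such as "structural", "crosslink", "combined".
#' @return an object of class `hinet`.
#' @export
hinet <- function(nodes, edges, granularity = "residue",
                  provenance = "structural") {
  nodes <- unique(nodes)
  if (anyDuplicated(nodes$node_id)) {
    dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
    stop("conflicting annotations for node(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(edges$interaction_class)) {
    edges$interaction_class <- rep(NA_character_, nrow(edges))
  }
  if (is.null(edges$evidence)) {
    edges$evidence <- replicate(nrow(edges), character(0), simplify = FALSE)
  }
  edges <- .canonical_edges(edges)
  bad <- setdiff(unique(c(edges$node_a, edges$node_b)), nodes$node_id)
  if (length(bad)) stop("edge endpoint(s) missing from node table: ",
                        paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, granularity = granularity,
                 provenance = provenance),
            class = "hinet")
}

.canonical_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  key <- paste(edges$node_a, edges$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    ev <- lapply(split(edges$evidence, grp),
                 function(l) unique(unlist(l)))
    first <- !duplicated(grp)
    merged <- edges[first, , drop = FALSE]
    merged$evidence <- ev[as.character(seq_along(ev))]
    edges <- merged
  }
  rownames(edges) <- NULL
  edges
}

#' @export
print.hinet <- function(x, ...) {
  cat("hinet [", x$granularity, "/", x$provenance, "]: ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

.residue_node_id <- function(role, mol, seq_pos, chain, resid) {
  ifelse(role == "dna",
         paste0(mol, ":", chain, ".", resid),
         paste0(mol, ":", seq_pos))
}

#' Build a residue-level network from interface edge tables
#'
#' Merges classified residue-level edges from one or more structures into a
#' simple graph. Protein residues are keyed by molecule id and sequence
#' position; edges whose protein residues lack a sequence position are
#' dropped (count reported via the `dropped_unmapped` attribute). DNA
#' nucleotides are keyed by chain and residue number. Duplicate edges across
#' structures merge with their structure ids accumulated as evidence.
#'
#' @param edge_tables a single edge table from [extract_interfaces()] or a
#'   list of them.
#' @return a `hinet` at residue granularity.
#' @export
build_residue_network <- function(edge_tables) {
  if (is.data.frame(edge_tables)) edge_tables <- list(edge_tables)
  ed <- do.call(rbind, edge_tables)
  empty_nodes <- data.frame(node_id = character(0),
                            node_class = character(0),
                            histone_type = character(0),
                            organism = character(0), stringsAsFactors = FALSE)
  if (is.null(ed) || !nrow(ed)) {
    return(hinet(empty_nodes,
                 data.frame(node_a = character(0), node_b = character(0)),
                 granularity = "residue", provenance = "structural"))
  }
  ed <- ed[ed$class %in% c("HHI", "HDI", "HPI", "DPI"), , drop = FALSE]
  unmapped <- (ed$role_a != "dna" & is.na(ed$seq_pos_a)) |
    (ed$role_b != "dna" & is.na(ed$seq_pos_b))
  n_drop <- sum(unmapped)
  ed <- ed[!unmapped, , drop = FALSE]

  na_id <- .residue_node_id(ed$role_a, ed$mol_a, ed$seq_pos_a,
                            ed$chain_a, ed$resid_a)
  nb_id <- .residue_node_id(ed$role_b, ed$mol_b, ed$seq_pos_b,
                            ed$chain_b, ed$resid_b)
  nodes <- unique(rbind(
    data.frame(node_id = na_id, node_class = ed$role_a,
               histone_type = ed$histone_type_a,
               organism = ed$organism, stringsAsFactors = FALSE),
    data.frame(node_id = nb_id, node_class = ed$role_b,
               histone_type = ed$histone_type_b,
               organism = ed$organism, stringsAsFactors = FALSE)))
  nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]
  edges <- data.frame(node_a = na_id, node_b = nb_id,
                      interaction_class = ed$class,
                      stringsAsFactors = FALSE)
  edges$evidence <- as.list(paste0("structural:", ed$structure_id))
  net <- hinet(nodes, edges, granularity = "residue",
               provenance = "structural")
  attr(net, "dropped_unmapped") <- n_drop
  net
}

#' Collapse a residue network to domain or protein granularity
#'
#' A collapsed edge exists between two coarse nodes iff at least one
#' residue-level edge connects their members; evidence sets are unioned.
#' Partner residues falling outside the domain map collapse onto the
#' whole-protein node. DNA collapses onto a single pseudo-node. Edges whose
#' endpoints collapse onto the same node (e.g. contacts between the two
#' copies of one histone variant) become self-loops and are dropped, with
#' the count reported via the `dropped_self` attribute.
#'
#' @param net a residue-level `hinet`.
#' @param to "protein" or "domain".
#' @param domain_map optional data.frame (protein, start, end, domain_id)
#'   assigning residue ranges to domain families.
#' @return a `hinet` at the requested granularity.
#' @export
collapse_granularity <- function(net, to = c("protein", "domain"),
                                 domain_map = NULL) {
  to <- match.arg(to)
  stopifnot(inherits(net, "hinet"))
  if (net$granularity != "residue") {
    stop("collapse_granularity expects a residue-level network")
  }
  if (!nrow(net$nodes)) {
    return(hinet(net$nodes, net$edges, granularity = to,
                 provenance = net$provenance))
  }
  map_node <- function(node_id, node_class) {
    prot <- sub(":.*$", "", node_id)
    if (node_class == "dna") return("DNA")
    if (to == "protein") return(prot)
    # domain level: histones stay whole proteins, partners map by range
    if (node_class == "histone" || is.null(domain_map)) return(prot)
    pos <- suppressWarnings(as.integer(sub("^.*:", "", node_id)))
    hit <- which(domain_map$protein == prot &
                   domain_map$start <= pos & domain_map$end >= pos)
    if (length(hit)) paste0(prot, ":", domain_map$domain_id[hit[1]]) else prot
  }
  coarse <- vapply(seq_len(nrow(net$nodes)), function(i)
    map_node(net$nodes$node_id[i], net$nodes$node_class[i]), character(1))
  lookup <- stats::setNames(coarse, net$nodes$node_id)

  nodes <- data.frame(node_id = coarse,
                      node_class = net$nodes$node_class,
                      histone_type = net$nodes$histone_type,
                      organism = net$nodes$organism,
                      stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]

  edges <- net$edges
  if (nrow(edges)) {
    edges$node_a <- unname(lookup[edges$node_a])
    edges$node_b <- unname(lookup[edges$node_b])
  }
  n_self <- sum(edges$node_a == edges$node_b)
  out <- hinet(nodes, edges, granularity = to, provenance = net$provenance)
  attr(out, "dropped_self") <- n_self
  out
}

#' Build a protein-level network from an external edge list
#'
#' Cross-link and high-throughput evidence enters at protein granularity
#' only. The edge list is a data.frame (node_a, node_b) with optional
#' node_class columns (class_a / class_b; default histone side unknown =>
#' partner).
#'
#' @param edge_df data.frame with node_a, node_b and optionally class_a,
#'   class_b ("histone:H3" style or "partner").
#' @param provenance evidence label ("crosslink" or "highthroughput").
#' @return a protein-level `hinet`.
#' @export
protein_network_from_edges <- function(edge_df, provenance = "crosslink") {
  cls_a <- edge_df$class_a %||% rep("partner", nrow(edge_df))
  cls_b <- edge_df$class_b %||% rep("partner", nrow(edge_df))
  nodes <- unique(data.frame(
    node_id = c(edge_df$node_a, edge_df$node_b),
    node_class = c(cls_a, cls_b),
    histone_type = NA_character_, organism = NA_character_,
    stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]
  edges <- data.frame(node_a = edge_df$node_a, node_b = edge_df$node_b,
                      interaction_class = NA_character_,
                      stringsAsFactors = FALSE)
  edges$evidence <- replicate(nrow(edges), provenance, simplify = FALSE)
  hinet(nodes, edges, granularity = "protein", provenance = provenance)
}

#' Merge networks of one granularity into a combined network
#'
#' Node and edge union; evidence provenance is preserved per edge so
#' per-source membership remains recoverable.
#'
#' @param nets list of `hinet` objects sharing granularity and id namespace.
#' @return combined `hinet`.
#' @export
merge_networks <- function(nets) {
  stopifnot(length(nets) >= 1)
  gran <- unique(vapply(nets, function(n) n$granularity, character(1)))
  if (length(gran) != 1) {
    stop("granularity mismatch: ", paste(gran, collapse = " vs "))
  }
  nodes <- do.call(rbind, lapply(nets, function(n) n$nodes))
  nodes <- unique(nodes)
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup)) {
    # same id with different annotation rows: conflict only if node_class
    # differs; fill NAs from the richer record first
    for (id in unique(dup)) {
      rows <- nodes[nodes$node_id == id, , drop = FALSE]
      if (length(unique(rows$node_class)) > 1) {
        stop("node class conflict for node '", id, "': ",
             paste(unique(rows$node_class), collapse = " vs "))
      }
    }
    merged <- nodes[!duplicated(nodes$node_id), , drop = FALSE]
    for (cl in c("histone_type", "organism")) {
      fill <- tapply(nodes[[cl]], nodes$node_id, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) as.character(v[1]) else NA_character_
      })
      merged[[cl]] <- as.character(fill[merged$node_id])
    }
    nodes <- merged
  }
  edges <- do.call(rbind, lapply(nets, function(n) n$edges))
  hinet(nodes, edges, granularity = gran, provenance = "combined")
}

#' Expand a network with one secondary interaction layer
#'
#' Adds partner-to-partner-of-partner edges whose at least one endpoint is an
#' existing partner node; new nodes enter as partners. Secondary edges
#' touching no existing node are dropped and counted.
#'
#' @param net a `hinet`.
#' @param secondary data.frame (node_a, node_b) of secondary edges.
#' @param evidence_tag evidence label for the added edges.
#' @return a `hinet` with provenance "global" and attribute
#'   `dropped_secondary`.
#' @export
expand_global <- function(net, secondary,
                          evidence_tag = "highthroughput") {
  stopifnot(inherits(net, "hinet"))
  if (is.null(secondary) || !nrow(secondary)) {
    out <- net
    out$provenance <- "global"
    attr(out, "dropped_secondary") <- 0L
    return(out)
  }
  keep <- secondary$node_a %in% net$nodes$node_id |
    secondary$node_b %in% net$nodes$node_id
  dropped <- sum(!keep)
  sec <- secondary[keep, , drop = FALSE]
  new_ids <- setdiff(unique(c(sec$node_a, sec$node_b)), net$nodes$node_id)
  nodes <- rbind(net$nodes,
                 data.frame(node_id = new_ids,
                            node_class = rep("partner", length(new_ids)),
                            histone_type = rep(NA_character_,
                                               length(new_ids)),
                            organism = rep(NA_character_, length(new_ids)),
                            stringsAsFactors = FALSE))
  add <- data.frame(node_a = sec$node_a, node_b = sec$node_b,
                    interaction_class = rep(NA_character_, nrow(sec)),
                    stringsAsFactors = FALSE)
  add$evidence <- replicate(nrow(add), evidence_tag, simplify = FALSE)
  out <- hinet(nodes, rbind(net$edges, add), granularity = net$granularity,
               provenance = "global")
  attr(out, "dropped_secondary") <- dropped
  out
}

#' Compare two networks by node and edge membership
#'
#' @param a,b `hinet` objects sharing an id namespace.
#' @return list with shared_nodes, only_a, only_b, shared_edges (canonical
#'   "a|b" strings) and the corresponding counts.
#' @export
compare_networks <- function(a, b) {
  na <- a$nodes$node_id; nb <- b$nodes$node_id
  ea <- paste(a$edges$node_a, a$edges$node_b, sep = "|")
  eb <- paste(b$edges$node_a, b$edges$node_b, sep = "|")
  res <- list(shared_nodes = sort(intersect(na, nb)),
              only_a = sort(setdiff(na, nb)),
              only_b = sort(setdiff(nb, na)),
              shared_edges = sort(intersect(ea, eb)))
  res$counts <- c(shared_nodes = length(res$shared_nodes),
                  only_a = length(res$only_a),
                  only_b = length(res$only_b),
                  shared_edges = length(res$shared_edges))
  res
}

#' Convert a network to an igraph graph
#' @param net a `hinet`.
#' @return igraph object (undirected, simple).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hinet"))
  igraph::graph_from_data_frame(
    d = net$edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes[, "node_id", drop = FALSE])
}

#' Export a network in SIF format
#'
#' One line per edge: `nodeA <tab> interaction_class <tab> nodeB` (class
#' falls back to "interacts" when untyped), readable by Cytoscape.
#'
#' @param net a `hinet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  cls <- net$edges$interaction_class
  cls[is.na(cls)] <- "interacts"
  writeLines(paste(net$edges$node_a, cls, net$edges$node_b, sep = "\t"),
             path)
  invisible(path)
}

#' Export node and edge tables as TSV
#' @param net a `hinet`.
#' @param nodes_path,edges_path output paths.
#' @return invisibly, the two paths.
#' @export
write_network_tsv <- function(net, nodes_path, edges_path) {
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed <- net$edges
  ed$evidence <- vapply(ed$evidence, paste, character(1), collapse = ";")
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Serialize / deserialize a network as JSON
#'
#' Round-trip format carrying nodes, edges and evidence sets.
#' @param net a `hinet`.
#' @param path JSON path.
#' @return `write_network_json` returns the path invisibly;
#'   `read_network_json` returns a `hinet`.
#' @export
write_network_json <- function(net, path) {
  obj <- list(granularity = net$granularity, provenance = net$provenance,
              nodes = net$nodes,
              edges = data.frame(node_a = net$edges$node_a,
                                 node_b = net$edges$node_b,
                                 interaction_class =
                                   net$edges$interaction_class,
                                 stringsAsFactors = FALSE),
              evidence = lapply(net$edges$evidence, as.character))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        interaction_class = character(0))
  }
  edges$evidence <- lapply(obj$evidence, as.character)
  hinet(as.data.frame(obj$nodes, stringsAsFactors = FALSE), edges,
        granularity = obj$granularity, provenance = obj$provenance)
}
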