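# Programmatic fixtures: everything is generated in code at test time.

# minimal hand-placed structure: arbitrary atoms on named chains
tiny_structure <- function(..., entity_names = NULL, id = "tiny") {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain_id = r$chain, residue_seq_id = r$resid,
               residue_name = r$resname %||fix% "ALA",
               atom_name = r$atom %||fix% "CA",
               element = r$element %||fix% "C",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               stringsAsFactors = FALSE)
  }))
  structure_from_atoms(atoms, entity_names = entity_names,
                       structure_id = id)
}

`%||fix%` <- function(a, b) if (is.null(a)) b else a

atom <- function(chain, resid, xyz, resname = "ALA", atom = "CA",
                 element = "C") {
  list(chain = chain, resid = resid, xyz = xyz, resname = resname,
       atom = atom, element = element)
}

# standard two-partner toy complex used by several tests
standard_toy <- function(seed = 101, dir = tempfile()) {
  spec <- toy_complex_spec(seed = seed)
  spec <- spec_add_partner(spec, "Partner One", length = 20,
    contacts = data.frame(target_chain = c("A", "C", "I"),
                          target_resid = c(10, 5, 30), contact = TRUE))
  spec <- spec_add_partner(spec, "Partner Two", length = 15,
    contacts = data.frame(target_chain = c("D", "J"),
                          target_resid = c(7, 100),
                          contact = c(TRUE, FALSE)),
    hydrogen_decoy = TRUE)
  spec$extra_contacts <- data.frame(
    chain_a = c("A", "B"), resid_a = c(20, 15),
    chain_b = c("B", "I"), resid_b = c(20, 15),
    contact = TRUE, dist = NA_real_)
  spec$ptm_sites <- data.frame(chain = "A", resid = 10, resname = "ALY")
  out <- generate_toy_complex(spec, dir = dir)
  st <- apply_residue_mapping(out$structure, "identity")
  ann <- classify_chains(st)
  ifc <- extract_interfaces(st, ann)
  list(gen = out, structure = st, annotations = ann, edges = ifc$edges,
       interface_residues = ifc$interface_residues)
}

# gap-free single-variant alignments matching the toy complex histones
toy_alignments <- function(len = 30) {
  row <- paste(rep("A", len), collapse = "")
  list(H3 = c(histone_h3.1 = row),
       H4 = c(histone_h4 = row),
       H2A = c(histone_h2a_type_1 = row),
       H2B = c(histone_h2b_type_1 = row))
}

# random residue-level network over a set of proteins (for collapse tests)
random_residue_network <- function(seed, n_proteins = 5, n_edges = 30) {
  set.seed(seed)
  prots <- paste0("prot", seq_len(n_proteins))
  mk_node <- function() {
    p <- sample(prots, 1)
    paste0(p, ":", sample(1:40, 1))
  }
  ea <- replicate(n_edges, mk_node())
  eb <- replicate(n_edges, mk_node())
  keep <- sub(":.*", "", ea) != sub(":.*", "", eb)
  ea <- ea[keep]; eb <- eb[keep]
  ids <- unique(c(ea, eb))
  nodes <- data.frame(node_id = ids,
                      node_class = ifelse(grepl("^prot[12]", ids),
                                          "histone", "partner"),
                      histone_type = NA_character_,
                      organism = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(node_a = ea, node_b = eb,
                      interaction_class = "HPI", stringsAsFactors = FALSE)
  edges$evidence <- replicate(nrow(edges), "structural:synthetic",
                              simplify = FALSE)
  hinet(nodes, edges, granularity = "residue", provenance = "structural")
}
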