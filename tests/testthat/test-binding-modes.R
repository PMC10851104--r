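# synthetic interface edge rows at the granularity classify_binding_mode and
# the hotspot profilers consume
edge_row <- function(class, mol_a, mol_b, pos_a = 1, chain_b = "I",
                     resid_b = 1, n = 1, sid = "s1", htype = "H3") {
  data.frame(structure_id = sid, class = class,
             chain_a = "A", resid_a = pos_a, resname_a = "ALA",
             seq_pos_a = pos_a, chain_b = chain_b, resid_b = resid_b,
             resname_b = "ALA", seq_pos_b = resid_b, min_dist = 4.5,
             n_atom_contacts = n, ptm_type = NA_character_,
             mol_a = mol_a, mol_b = mol_b,
             role_a = if (class == "DPI") "partner" else "histone",
             role_b = switch(class, HPI = "partner", HHI = "histone",
                             HDI = "dna", DPI = "dna"),
             histone_type_a = if (class == "DPI") NA_character_ else htype,
             histone_type_b = NA_character_, organism = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("representative selection recovers each planted scenario", {
  md <- data.frame(
    structure_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"),
    partner_id = c("p1", "p1", "p1", "p2", "p3", "p4", "p4"),
    resolution = c(2.0, 3.0, 2.5, 2.2, 1.9, 2.8, 3.1),
    has_mutations = FALSE,
    partner_length = c(100, 100, 100, 8, 50, 60, 60),
    n_core_histone_chains = c(8, 8, 8, 8, 6, 8, 8),
    n_lost_bp = c(0, 0, 0, 0, 0, 25, 0),
    stringsAsFactors = FALSE)
  shared <- c("H3:1", "H3:2", "H3:3", "H3:4")
  md$interface <- list(c(shared, "H3:5"),       # mode 1, 2.0 A
                       c("H4:9", "H4:10", "H2A:3"),  # distinct mode
                       c(shared, "H3:5"),       # redundant with s1, worse
                       list("H4:1")[[1]],       # short peptide -> dropped
                       "H2A:1",                 # subnucleosomal -> dropped
                       "DNA:I.1",               # lost-DNA -> dropped
                       "DNA:I.2")               # p4 survivor
  sel <- select_representatives(md)
  expect_setequal(sel$structure_id, c("s1", "s2", "s7"))
  # redundant pair keeps the higher resolution member
  expect_true("s1" %in% sel$structure_id && !"s3" %in% sel$structure_id)
  # multi-mode partner keeps one structure per mode
  expect_equal(sum(sel$partner_id == "p1"), 2)
  # idempotence
  sel2 <- select_representatives(sel)
  expect_equal(sel2$structure_id, sel$structure_id)
})

test_that("mutation-free structures are preferred within a redundant group", {
  md <- data.frame(structure_id = c("m1", "m2"), partner_id = "p",
                   resolution = c(1.5, 2.5), has_mutations = c(TRUE, FALSE),
                   partner_length = 50, n_core_histone_chains = 8,
                   n_lost_bp = 0, stringsAsFactors = FALSE)
  md$interface <- list(c("H3:1", "H3:2"), c("H3:1", "H3:2"))
  sel <- select_representatives(md)
  expect_equal(sel$structure_id, "m2")

  md$resolution <- c(1.5, NA)
  expect_error(select_representatives(md), "missing resolution")
})

test_that("complex metadata measures cores, lost base pairs and lengths", {
  spec <- toy_complex_spec(seed = 81, dna_length = 40,
                           histone_chain_length = 10)
  spec <- spec_add_partner(spec, "Partner One", length = 12,
    contacts = data.frame(target_chain = "A", target_resid = 5,
                          contact = TRUE))
  # anchor every other base pair of strand I on the octamer (18 base pairs
  # touched, 22 lost); probes live on chains B..G, away from the partner
  # anchor A:5
  ec <- data.frame(
    chain_a = "I", resid_a = seq(2, 36, by = 2),
    chain_b = rep(c("B", "C", "D", "E", "F", "G"), length.out = 18),
    resid_b = rep(1:9, length.out = 18),
    contact = TRUE, dist = NA_real_)
  spec$extra_contacts <- ec[!duplicated(paste(ec$chain_b, ec$resid_b)), ]
  out <- generate_toy_complex(spec, dir = withr::local_tempdir())
  st <- apply_residue_mapping(out$structure, "identity")
  ann <- classify_chains(st)
  ed <- extract_interfaces(st, ann)$edges
  md <- complex_metadata(st, ann, ed)
  expect_equal(md$n_core_histone_chains, 8)
  expect_equal(md$partner_length, 12)
  expect_equal(md$n_lost_bp,
               40 - length(unique(spec$extra_contacts$resid_a)))
  expect_true(all(c("histone_h3.1:5") %in% md$interface[[1]]))
})

test_that("binding modes partition contacting partners", {
  edges <- rbind(edge_row("DPI", "pDna", "DNA"),
                 edge_row("HPI", "histone_h2a", "pHis"),
                 edge_row("HPI", "histone_h2b", "pBoth"),
                 edge_row("DPI", "pBoth", "DNA"))
  lab <- classify_binding_mode(edges)
  modes <- setNames(lab$mode, lab$partner_id)
  expect_equal(unname(modes["pDna"]), "dna_only")
  expect_equal(unname(modes["pHis"]), "histone_only")
  expect_equal(unname(modes["pBoth"]), "both")

  expect_warning(lab2 <- classify_binding_mode(edges,
                                               partner_ids = c("pDna", "pNone")),
                 "without contacts")
  expect_equal(lab2$mode[lab2$partner_id == "pNone"], "none")

  # fractions sum to one over contacting partners
  expect_equal(sum(binding_mode_fractions(lab)), 1)
})

test_that("planted 65/20/15 mode composition is recovered exactly", {
  edges <- list()
  for (i in 1:65) {
    p <- sprintf("both%02d", i)
    edges[[length(edges) + 1]] <- edge_row("HPI", "histone_h3", p)
    edges[[length(edges) + 1]] <- edge_row("DPI", p, "DNA")
  }
  for (i in 1:20) {
    edges[[length(edges) + 1]] <-
      edge_row("HPI", "histone_h3", sprintf("his%02d", i))
  }
  for (i in 1:15) {
    edges[[length(edges) + 1]] <-
      edge_row("DPI", sprintf("dna%02d", i), "DNA")
  }
  lab <- classify_binding_mode(do.call(rbind, edges))
  fr <- binding_mode_fractions(lab)
  expect_equal(unname(fr["both"]), 0.65)
  expect_equal(unname(fr["histone_only"]), 0.20)
  expect_equal(unname(fr["dna_only"]), 0.15)
})

test_that("consensus mapping handles gaps, insertions and errors", {
  aln <- c(varA = "AR-TK--QT", varB = "--STKAAQT")
  m <- map_to_consensus(data.frame(variant = c("varA", "varA", "varB"),
                                   position = c(2, 5, 7)), aln)
  expect_equal(m$consensus_position, c(2, 8, 9))
  # residue with two upstream gap columns in its row shifts by two
  m2 <- map_to_consensus(data.frame(variant = "varA", position = 3), aln)
  expect_equal(m2$consensus_position, 4)
  # insertion-only column flagged
  m3 <- map_to_consensus(data.frame(variant = "varB", position = 1), aln)
  expect_true(m3$insertion_only)

  expect_error(map_to_consensus(data.frame(variant = "varC", position = 1),
                                aln), "missing from alignment")
  expect_error(map_to_consensus(data.frame(variant = "varA", position = 10),
                                aln), "beyond")
})

test_that("alignment round-trips through aligned FASTA", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">varA", "AR-TK--QT", ">varB", "--STKAAQT"), p)
  aln <- read_alignment(p)
  expect_equal(unname(aln["varA"]), "AR-TK--QT")
})

test_that("histone hotspot counts are exact, partner chains merged", {
  # partner via two chains of one molecule counts once
  spec <- toy_complex_spec(seed = 83)
  spec <- spec_add_partner(spec, "Dimeric Reader", length = 10,
    contacts = data.frame(target_chain = "A", target_resid = 10,
                          contact = TRUE))
  spec <- spec_add_partner(spec, "Dimeric Reader", length = 10,
    contacts = data.frame(target_chain = "A", target_resid = 10,
                          contact = TRUE))
  spec <- spec_add_partner(spec, "Second Partner", length = 10,
    contacts = data.frame(target_chain = "A", target_resid = 10,
                          contact = TRUE))
  out <- generate_toy_complex(spec, dir = withr::local_tempdir())
  st <- apply_residue_mapping(out$structure, "identity")
  ed <- extract_interfaces(st, classify_chains(st))$edges
  prof <- profile_histone_hotspots(ed, toy_alignments())
  at10 <- prof[prof$histone_type == "H3" & prof$consensus_position == 10, ]
  expect_equal(at10$unique_partners, 2)  # dimeric reader counted once
  untouched <- prof[prof$histone_type == "H4", ]
  expect_true(all(untouched$unique_partners == 0))
  expect_true(all(untouched$mean_contacts == 0))
})

test_that("DNA hotspots pair strands and default the dyad to the midpoint", {
  spec <- toy_complex_spec(seed = 85)  # 147 bp duplex
  # one partner touches both strands of the same base pair (bp 40):
  # strand I nucleotide 40 pairs with strand J nucleotide 147 + 1 - 40 = 108
  spec <- spec_add_partner(spec, "Bridger", length = 10,
    contacts = data.frame(target_chain = c("I", "J"),
                          target_resid = c(40, 108), contact = TRUE))
  spec <- spec_add_partner(spec, "Edge Binder", length = 10,
    contacts = data.frame(target_chain = "I", target_resid = 20,
                          contact = TRUE))
  out <- generate_toy_complex(spec, dir = withr::local_tempdir())
  st <- apply_residue_mapping(out$structure, "identity")
  ann <- classify_chains(st)
  ed <- extract_interfaces(st, ann)$edges
  prof <- profile_dna_hotspots(ed, structures = list(toy_complex = st),
                               annotations_list = list(toy_complex = ann))
  # dyad defaults to ceiling(147 / 2) = 74
  expect_setequal(prof$bp, c(40 - 74, 20 - 74))
  expect_equal(prof$unique_partners[prof$bp == 40 - 74], 1)  # not 2
  expect_equal(prof$unique_partners[prof$bp == 20 - 74], 1)
  expect_equal(prof$shl[prof$bp == 20 - 74], round((20 - 74) / 10))

  # explicit dyad shifts the frame
  prof2 <- profile_dna_hotspots(ed, structures = list(toy_complex = st),
                                annotations_list = list(toy_complex = ann),
                                dyad_config = c(toy_complex = 40))
  expect_true(0 %in% prof2$bp)
})

test_that("strand length mismatch beyond tolerance raises an error", {
  st <- tiny_structure(
    atom("I", 1, c(0, 0, 0), resname = "DA", atom = "P", element = "P"),
    atom("I", 2, c(7, 0, 0), resname = "DT", atom = "P", element = "P"),
    atom("I", 3, c(14, 0, 0), resname = "DG", atom = "P", element = "P"),
    atom("I", 4, c(21, 0, 0), resname = "DC", atom = "P", element = "P"),
    atom("I", 5, c(28, 0, 0), resname = "DA", atom = "P", element = "P"),
    atom("I", 6, c(35, 0, 0), resname = "DT", atom = "P", element = "P"),
    atom("J", 1, c(0, 9, 0), resname = "DT", atom = "P", element = "P"))
  expect_error(histonet:::.dna_strand_index(st, c("I", "J")),
               "length mismatch")
})

test_that("functional-class comparison flags positions shared by partners", {
  spec <- toy_complex_spec(seed = 87)
  spec <- spec_add_partner(spec, "Remodeler A", length = 10,
    contacts = data.frame(target_chain = "A", target_resid = 15,
                          contact = TRUE))
  spec <- spec_add_partner(spec, "Remodeler B", length = 10,
    contacts = data.frame(target_chain = c("A", "E"),
                          target_resid = c(15, 8), contact = TRUE))
  out <- generate_toy_complex(spec, dir = withr::local_tempdir())
  st <- apply_residue_mapping(out$structure, "identity")
  ed <- extract_interfaces(st, classify_chains(st))$edges
  fa <- data.frame(structure_id = "toy_complex", class = "Remodeler")
  cmp <- compare_modes_by_function(ed, toy_alignments(), fa)
  shared <- cmp[cmp$consensus_position == 15 & cmp$histone_type == "H3", ]
  expect_true(shared$shared)
  expect_equal(shared$n_partners, 2)
  solo <- cmp[cmp$consensus_position == 8, ]
  expect_false(solo$shared)

  # unannotated structures fall into "unclassified" with a warning
  expect_warning(
    cmp2 <- compare_modes_by_function(
      ed, toy_alignments(),
      data.frame(structure_id = "other", class = "x")),
    "unclassified")
  expect_true(all(cmp2$class == "unclassified"))
})
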