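mk_edges <- function(seed, pname) {
  spec <- toy_complex_spec(seed = seed)
  spec <- spec_add_partner(spec, pname, length = 20,
    contacts = data.frame(target_chain = c("A", "I"),
                          target_resid = c(10, 30), contact = TRUE))
  spec$extra_contacts <- data.frame(chain_a = "A", resid_a = 20,
                                    chain_b = "B", resid_b = 20,
                                    contact = TRUE, dist = NA_real_)
  out <- generate_toy_complex(spec, dir = withr::local_tempdir(),
                              name = paste0("toy", seed))
  st <- apply_residue_mapping(out$structure, "identity")
  extract_interfaces(st, classify_chains(st))$edges
}

test_that("residue networks deduplicate shared edges and accumulate evidence", {
  e1 <- mk_edges(201, "Partner X")
  e2 <- mk_edges(202, "Partner X")
  net <- build_residue_network(list(e1, e2))
  expect_s3_class(net, "hinet")
  expect_equal(nrow(net$edges), 3)  # same planted edges in both structures
  ev <- net$edges$evidence[[which(net$edges$interaction_class == "HPI")]]
  expect_setequal(ev, c("structural:toy201", "structural:toy202"))

  # disjoint structures: edge count adds
  e3 <- mk_edges(203, "Partner Y")
  net2 <- build_residue_network(list(e1, e3))
  expect_equal(nrow(net2$edges), 5)  # HHI shared, HPI/DPI distinct partners

  # empty input
  empty <- build_residue_network(list())
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("unmapped protein residues are dropped with a count", {
  e1 <- mk_edges(205, "Partner X")
  e1$seq_pos_a[1] <- NA
  net <- build_residue_network(e1)
  expect_equal(attr(net, "dropped_unmapped"), 1L)
  expect_equal(nrow(net$edges), 2)
})

test_that("granularity collapse is sound and counts many-to-one edges once", {
  # 5 residue edges between one histone and one partner -> 1 protein edge
  nodes <- data.frame(
    node_id = c(paste0("H4:", 1:5), paste0("pX:", 11:15)),
    node_class = rep(c("histone", "partner"), each = 5),
    histone_type = rep(c("H4", NA), each = 5),
    organism = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(node_a = paste0("H4:", 1:5),
                      node_b = paste0("pX:", 11:15),
                      interaction_class = "HPI", stringsAsFactors = FALSE)
  edges$evidence <- replicate(5, "structural:s1", simplify = FALSE)
  net <- hinet(nodes, edges)
  prot <- collapse_granularity(net, "protein")
  expect_equal(nrow(prot$edges), 1)
  expect_setequal(prot$nodes$node_id, c("H4", "pX"))

  # residues in two domains of one partner -> 2 domain edges, 1 protein edge
  dmap <- data.frame(protein = "pX", start = c(1, 13), end = c(12, 30),
                     domain_id = c("PHD", "BROMO"))
  dom <- collapse_granularity(net, "domain", domain_map = dmap)
  expect_equal(nrow(dom$edges), 2)
  expect_setequal(dom$nodes$node_id[dom$nodes$node_class == "partner"],
                  c("pX:PHD", "pX:BROMO"))

  # collapse of an empty network stays empty
  empty <- build_residue_network(list())
  expect_equal(nrow(collapse_granularity(empty, "protein")$edges), 0)
})

test_that("collapse matches the brute-force member relation on random nets", {
  for (s in 1:6) {
    net <- random_residue_network(seed = 500 + s)
    prot <- collapse_granularity(net, "protein")
    got <- sort(paste(prot$edges$node_a, prot$edges$node_b))
    pa <- sub(":.*", "", net$edges$node_a)
    pb <- sub(":.*", "", net$edges$node_b)
    lo <- pmin(pa, pb); hi <- pmax(pa, pb)
    want <- sort(unique(paste(lo, hi)[lo != hi]))
    expect_equal(got, want)
  }
})

test_that("merging unions nodes and edges with inclusion-exclusion", {
  # structural 10 edges, crosslink 8 edges, 3 shared -> 15 in the union
  mk <- function(partners, tag) {
    protein_network_from_edges(
      data.frame(node_a = "H3", node_b = partners,
                 class_a = "histone", class_b = "partner",
                 stringsAsFactors = FALSE), tag)
  }
  a <- mk(sprintf("p%02d", 1:10), "structural")
  b <- mk(sprintf("p%02d", 8:15), "crosslink")
  comb <- merge_networks(list(a, b))
  expect_equal(nrow(comb$edges), 15)
  shared_ev <- comb$edges$evidence[[match("p08", comb$edges$node_b)]]
  expect_setequal(shared_ev, c("structural", "crosslink"))

  # merge of one network is the identity on nodes/edges
  solo <- merge_networks(list(a))
  expect_setequal(solo$nodes$node_id, a$nodes$node_id)
  expect_equal(nrow(solo$edges), nrow(a$edges))

  # conflicting node classes are an error naming the node
  c1 <- protein_network_from_edges(
    data.frame(node_a = "H3", node_b = "pZ",
               class_a = "histone", class_b = "partner"), "structural")
  c2 <- protein_network_from_edges(
    data.frame(node_a = "pZ", node_b = "other",
               class_a = "histone", class_b = "partner"), "crosslink")
  expect_error(merge_networks(list(c1, c2)), "pZ")

  # granularity mismatch
  res <- random_residue_network(1)
  expect_error(merge_networks(list(a, res)), "granularity mismatch")
})

test_that("global expansion adds one partner layer and never removes", {
  base <- protein_network_from_edges(
    data.frame(node_a = "H3", node_b = "pA",
               class_a = "histone", class_b = "partner"), "structural")
  glob <- expand_global(base, data.frame(node_a = "pA", node_b = "pB"))
  expect_equal(nrow(glob$nodes), 3)
  expect_equal(nrow(glob$edges), 2)
  expect_equal(glob$nodes$node_class[glob$nodes$node_id == "pB"], "partner")

  # untethered secondary edge is dropped and counted
  glob2 <- expand_global(base, data.frame(node_a = "pC", node_b = "pD"))
  expect_equal(attr(glob2, "dropped_secondary"), 1L)
  expect_equal(nrow(glob2$edges), 1)

  # empty secondary list is the identity
  glob3 <- expand_global(base, NULL)
  expect_equal(nrow(glob3$edges), nrow(base$edges))
  expect_true(nrow(glob$edges) >= nrow(base$edges))
})

test_that("network comparison is plain set algebra", {
  mk <- function(partners) protein_network_from_edges(
    data.frame(node_a = "H3", node_b = partners,
               class_a = "histone", class_b = "partner"), "structural")
  a <- mk(c("x", "y", "z")); b <- mk(c("y", "z", "w"))
  cmp <- compare_networks(a, b)
  expect_setequal(cmp$shared_nodes, c("H3", "y", "z"))
  expect_equal(cmp$only_a, "x")
  expect_equal(cmp$only_b, "w")
  same <- compare_networks(a, a)
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
  expect_equal(length(compare_networks(mk("x"), mk("q"))$shared_edges), 0)
})

test_that("SIF, TSV and JSON exports round-trip the network", {
  net <- random_residue_network(42)
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\tHPI\t", lines, fixed = TRUE)))

  write_network_tsv(net, file.path(dir, "nodes.tsv"),
                    file.path(dir, "edges.tsv"))
  nd <- read.delim(file.path(dir, "nodes.tsv"))
  expect_equal(nrow(nd), nrow(net$nodes))

  js <- file.path(dir, "net.json")
  write_network_json(net, js)
  back <- read_network_json(js)
  expect_equal(back$granularity, net$granularity)
  expect_setequal(back$nodes$node_id, net$nodes$node_id)
  expect_setequal(paste(back$edges$node_a, back$edges$node_b),
                  paste(net$edges$node_a, net$edges$node_b))
  expect_setequal(unlist(back$edges$evidence), unlist(net$edges$evidence))
})
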