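write_mutation_tsv <- function(df) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

mut_row <- function(gene = "H3C1", change = "R29P", sample = "s1",
                    vclass = "missense", seqtype = "wxs",
                    somatic = "matched", tmb = 5, dbsnp = FALSE,
                    cancer = "Breast Cancer") {
  data.frame(gene = gene, protein_change = change, sample_id = sample,
             cancer_type = cancer, variant_class = vclass,
             sequencing_type = seqtype, somatic_status = somatic,
             sample_tmb = tmb, in_dbsnp = dbsnp, stringsAsFactors = FALSE)
}

test_that("protein-change strings decompose; malformed rows are rejected", {
  tab <- rbind(mut_row("H2AC11", "R29P"), mut_row("H3C1", "K27M", "s2"),
               mut_row("H3C1", "R29", "s3"), mut_row("H3C1", "27M", "s4"))
  parsed <- parse_mutations(write_mutation_tsv(tab))
  expect_equal(nrow(parsed$records), 2)
  expect_equal(parsed$records$wt_aa, c("R", "K"))
  expect_equal(parsed$records$position, c(29, 27))
  expect_equal(parsed$records$mut_aa, c("P", "M"))
  expect_equal(nrow(parsed$rejects), 2)
  expect_true(all(parsed$rejects$reason == "unparseable protein change"))

  expect_error(parse_mutations(write_mutation_tsv(tab[, -1])),
               "gene")
})

test_that("combined set drops targeted, unmatched and non-missense records", {
  tab <- rbind(
    mut_row(change = "A10V", sample = "s1"),
    mut_row(change = "A11V", sample = "s2"),
    mut_row(change = "A12V", sample = "s3"),
    mut_row(change = "A13V", sample = "s4"),
    mut_row(change = "A14V", sample = "s5"),
    mut_row(change = "A15V", sample = "s6", seqtype = "targeted"),
    mut_row(change = "A16V", sample = "s7", seqtype = "targeted"),
    mut_row(change = "A17V", sample = "s8", seqtype = "targeted"),
    mut_row(change = "A18V", sample = "s9", somatic = "unmatched"),
    mut_row(change = "R20*", sample = "s10", vclass = "nonsense"))
  parsed <- parse_mutations(write_mutation_tsv(tab))
  comb <- build_combined_set(parsed$records)
  expect_equal(nrow(comb$records), 5)

  # record present in both sources is counted once
  comb2 <- build_combined_set(parsed$records, parsed$records)
  expect_equal(nrow(comb2$records), 5)

  # empty input
  empty <- build_combined_set(parsed$records[0, ])
  expect_equal(nrow(empty$records), 0)
})

test_that("refined set applies strict TMB, dbSNP and recurrence filters", {
  tab <- rbind(
    # recurrent in 3 clean samples: retained
    mut_row(change = "R29P", sample = "r1"),
    mut_row(change = "R29P", sample = "r2"),
    mut_row(change = "R29P", sample = "r3"),
    # recurrent in only 2 samples: dropped
    mut_row(change = "K36M", sample = "r1"),
    mut_row(change = "K36M", sample = "r2"),
    # TMB 11 sample: dropped (strict > 10); TMB exactly 10 is kept
    mut_row(change = "E50D", sample = "h1", tmb = 11),
    mut_row(change = "E50D", sample = "h2", tmb = 11),
    mut_row(change = "E50D", sample = "h3", tmb = 11),
    mut_row(change = "G34R", sample = "t1", tmb = 10),
    mut_row(change = "G34R", sample = "t2", tmb = 10),
    mut_row(change = "G34R", sample = "t3", tmb = 10),
    # dbSNP-known recurrent mutation: dropped
    mut_row(change = "T45S", sample = "d1", dbsnp = TRUE),
    mut_row(change = "T45S", sample = "d2", dbsnp = TRUE),
    mut_row(change = "T45S", sample = "d3", dbsnp = TRUE))
  comb <- build_combined_set(parse_mutations(write_mutation_tsv(tab))$records)
  ref <- build_refined_set(comb)
  expect_setequal(ref$recurrence$mutation, c("H3C1:R29P", "H3C1:G34R"))
  expect_equal(nrow(ref$records), 6)
  expect_true(all(ref$recurrence$n_samples >= 3))

  # TMB derivation: samples without the column derive count / callable Mb
  tab2 <- tab
  tab2$sample_tmb <- NA
  comb2 <- build_combined_set(parse_mutations(write_mutation_tsv(tab2))$records)
  ref2 <- build_refined_set(comb2)        # all derived TMBs are tiny
  expect_equal(nrow(ref2$recurrence), 3)  # E50D no longer TMB-filtered
  expect_error(build_refined_set(comb2, derive_tmb = FALSE), "underivable")
})

test_that("monotonicity: every filter only removes records", {
  for (s in 1:25) {
    set.seed(900 + s)
    n <- sample(20:60, 1)
    tab <- do.call(rbind, lapply(seq_len(n), function(i) {
      mut_row(gene = sample(c("H3C1", "H4C1", "H1-4"), 1),
              change = paste0(sample(c("R", "K", "E"), 1),
                              sample(1:60, 1), sample(c("P", "M", "Q"), 1)),
              sample = sprintf("s%02d", sample(1:12, 1)),
              vclass = sample(c("missense", "nonsense"), 1,
                              prob = c(0.8, 0.2)),
              seqtype = sample(c("wxs", "wgs", "targeted"), 1),
              somatic = sample(c("matched", "unmatched"), 1,
                               prob = c(0.85, 0.15)),
              tmb = round(stats::runif(1, 1, 20), 1),
              dbsnp = stats::runif(1) < 0.1)
    }))
    parsed <- parse_mutations(write_mutation_tsv(tab))
    comb <- build_combined_set(parsed$records)
    ref <- build_refined_set(comb)
    expect_lte(nrow(comb$records), nrow(parsed$records))
    expect_lte(nrow(ref$records), nrow(comb$records))
    keys_c <- paste(comb$records$gene, comb$records$protein_change,
                    comb$records$sample_id)
    keys_r <- paste(ref$records$gene, ref$records$protein_change,
                    ref$records$sample_id)
    expect_true(all(keys_r %in% keys_c))
  }
})

test_that("interface mapping matches a brute-force edge-table scan", {
  gen <- generate_mutation_table(mutation_table_spec(seed = 5),
                                 dir = withr::local_tempdir())
  parsed <- parse_mutations(gen$tsv_path)
  ref <- build_refined_set(build_combined_set(parsed$records))
  net <- read_network_json(gen$network_path)
  mp <- map_mutations_to_interfaces(ref, net)

  # brute force: scan the edge table for each mutation key
  uniq <- ref$records[!duplicated(paste(ref$records$gene,
                                        ref$records$protein_change)), ]
  for (i in seq_len(nrow(uniq))) {
    key <- paste0(uniq$gene[i], ":", uniq$protein_change[i])
    nid <- paste0(uniq$gene[i], ":", uniq$position[i])
    for (cls in c("HDI", "HHI", "HPI")) {
      hit <- any(net$edges$interaction_class == cls &
                   (net$edges$node_a == nid | net$edges$node_b == nid))
      expect_equal(key %in% mp$per_class[[cls]], hit)
    }
  }
  # a mutation at a non-interface position is unmapped
  fake <- ref
  fake$records <- rbind(ref$records[1, ], ref$records[1, ])
  fake$records$position[2] <- 9999
  fake$records$protein_change[2] <- "A9999V"
  mp2 <- map_mutations_to_interfaces(fake, net)
  expect_true(any(grepl("9999", mp2$unmapped)))
})

test_that("multi-class mutations appear in every matching list", {
  nodes <- data.frame(node_id = c("H3C1:27", "H4C1:1", "DNA:I.5", "pX:9"),
                      node_class = c("histone", "histone", "dna", "partner"),
                      histone_type = NA_character_,
                      organism = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(node_a = c("H3C1:27", "H3C1:27", "H3C1:27"),
                      node_b = c("H4C1:1", "DNA:I.5", "pX:9"),
                      interaction_class = c("HHI", "HDI", "HPI"),
                      stringsAsFactors = FALSE)
  edges$evidence <- replicate(3, "structural:s", simplify = FALSE)
  net <- hinet(nodes, edges)
  mset <- list(records = data.frame(
    gene = "H3C1", protein_change = "K27M", sample_id = "s1",
    wt_aa = "K", position = 27, mut_aa = "M", stringsAsFactors = FALSE))
  mp <- map_mutations_to_interfaces(mset, net)
  expect_true(all(vapply(mp$per_class, function(v) "H3C1:K27M" %in% v,
                         logical(1))))
  expect_equal(mp$multi, "H3C1:K27M")
})

test_that("physicochemical partition is total and bookkeeping is exact", {
  expect_equal(classify_physchem("K"), "positive")
  expect_equal(classify_physchem("E"), "negative")
  expect_equal(classify_physchem("F"), "nonpolar_aromatic")
  expect_equal(classify_physchem("S"), "polar_uncharged")
  expect_equal(classify_physchem("G"), "nonpolar_aliphatic")
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_length(classify_physchem(aa20), 20)
  expect_error(classify_physchem("B"), "nonstandard")

  prof <- profile_interface_change(
    data.frame(wt_aa = rep("R", 10), mut_aa = rep("L", 10)))
  expect_equal(prof$wt_count[prof$category == "positive"], 10)
  expect_equal(prof$mut_count[prof$category == "positive"], 0)
  expect_equal(prof$mut_count[prof$category == "nonpolar_aliphatic"], 10)
})

test_that("ddG prediction prunes partners for HHI/HDI but not HPI", {
  toy <- standard_toy(seed = 121)
  seen <- new.env()
  probe <- function(structure, chain, position, wt, mut, mode) {
    seen$chains <- structure$chains$chain_id
    seen$mode <- mode
    1.0
  }
  attr(probe, "predictor_id") <- "probe"
  mut <- list(gene = "histone_h3.1", position = 10, wt_aa = "K",
              mut_aa = "M")

  r1 <- predict_ddg(mut, toy$structure, toy$annotations, "HHI",
                    predictor = probe)
  expect_false(any(c("P", "Q") %in% seen$chains))
  expect_equal(seen$mode, "protein-protein")
  expect_equal(r1$status, "ok")

  predict_ddg(mut, toy$structure, toy$annotations, "HDI", predictor = probe)
  expect_equal(seen$mode, "protein-dna")
  expect_false(any(c("P", "Q") %in% seen$chains))

  predict_ddg(mut, toy$structure, toy$annotations, "HPI", predictor = probe)
  expect_true(all(c("P", "Q") %in% seen$chains))

  # absent position: skipped with reason, not fatal
  mut2 <- list(gene = "histone_h3.1", position = 999, wt_aa = "K",
               mut_aa = "M")
  r2 <- predict_ddg(mut2, toy$structure, toy$annotations, "HHI",
                    predictor = probe)
  expect_equal(r2$status, "skipped")
  expect_true(is.na(r2$ddg))

  # predictor failure recorded
  boom <- function(...) stop("model exploded")
  r3 <- predict_ddg(mut, toy$structure, toy$annotations, "HHI",
                    predictor = boom)
  expect_equal(r3$status, "predictor_error")
})

test_that("the surrogate predictor is deterministic and charge-driven", {
  sur <- ddg_surrogate_predictor()
  a <- sur(NULL, "A", 29, "R", "E", "protein-protein")
  b <- sur(NULL, "A", 29, "R", "E", "protein-protein")
  expect_identical(a, b)
  expect_gt(sur(NULL, "A", 1, "R", "E", "protein-dna"),
            sur(NULL, "A", 1, "L", "I", "protein-dna"))
})

test_that("disruptive selection honors thresholds and the recurrence gate", {
  recur <- data.frame(mutation = c("g:R1E", "g:K2D", "g:E3K", "g:L4I"),
                      n_samples = c(3, 3, 2, 5))
  dd <- rbind(
    data.frame(mutation = "g:R1E", interaction_class = "HDI", ddg = 1.2,
               structure_id = "s1"),    # >= 1.0 -> selected
    data.frame(mutation = "g:K2D", interaction_class = "HHI", ddg = 1.4,
               structure_id = "s1"),    # < 1.5 -> not selected
    data.frame(mutation = "g:E3K", interaction_class = "HPI", ddg = 2.0,
               structure_id = "s1"),    # recurrence 2 -> not selected
    data.frame(mutation = "g:L4I", interaction_class = "HPI", ddg = 1.6,
               structure_id = "s1"))    # selected
  sel <- select_disruptive(dd, recur)
  expect_setequal(sel$mutation, c("g:R1E", "g:L4I"))

  # invariant to record order and duplicated per-structure rows
  dd_shuffled <- dd[c(4, 2, 1, 3), ]
  dd_dup <- rbind(dd, dd[1, ])
  expect_equal(select_disruptive(dd_shuffled, recur)$mutation,
               sel$mutation)
  expect_equal(select_disruptive(dd_dup, recur)$mean_ddg, sel$mean_ddg)

  # multi-structure mean
  dd2 <- rbind(data.frame(mutation = "g:R1E", interaction_class = "HDI",
                          ddg = 0.8, structure_id = "s1"),
               data.frame(mutation = "g:R1E", interaction_class = "HDI",
                          ddg = 1.6, structure_id = "s2"))
  sel2 <- select_disruptive(dd2, recur)
  expect_equal(sel2$mean_ddg, 1.2)
  expect_equal(sel2$n_structures, 2L)
})

test_that("Tukey HSD comparisons flag separated groups and reject degenerate input", {
  set.seed(11)
  vals <- c(rnorm(20, 0), rnorm(20, 5))
  grp <- rep(c("H2A", "H3"), each = 20)
  cmp <- compare_ddg_groups(vals, grp)
  expect_true(cmp$sig_005)
  expect_equal(nrow(cmp), 1)
  med <- attr(cmp, "medians")
  expect_lt(med[["H2A"]], med[["H3"]])

  expect_error(compare_ddg_groups(rnorm(5), rep("a", 5)), "two groups")
  expect_error(compare_ddg_groups(c(1, 2, 3), c("a", "a", "b")),
               "degenerate")
})
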