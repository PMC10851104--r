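# Seeded synthetic-data generators with planted ground truth.
#
# The toy nucleosome complex is deliberately non-physical: poly-alanine
# backbones with one designated contact atom per residue, chains laid out on
# well-separated rows so that the ONLY inter-chain proximities are the
# planted ones. Planted contacts sit in [cutoff - 0.5, cutoff - 0.1] and
# planted non-contacts in [cutoff + 0.1, cutoff + 2.0]; the +-0.1 A band
# around the cutoff is never used. Geometry is re-verified against an
# all-pairs distance scan before the truth sidecar is written.

.CHAIN_ROW_SPACING <- 100
.RESIDUE_SPACING <- 14

#' Default toy nucleosome complex specification
#'
#' Eight core histone chains (two copies each of H3, H4, H2A, H2B), a
#' 147-bp DNA duplex and a configurable set of partner chains with planted
#' contacts.
#'
#' @param seed integer seed.
#' @param dna_length duplex length in base pairs.
#' @param histone_chain_length residues per histone chain.
#' @return a spec list consumed by [generate_toy_complex()].
#' @export
toy_complex_spec <- function(seed = 1, dna_length = 147,
                             histone_chain_length = 30) {
  list(
    seed = seed,
    histone_chain_length = histone_chain_length,
    dna_length = dna_length,
    histone_entities = c(A = "Histone H3.1", B = "Histone H4",
                         C = "Histone H2A type 1", D = "Histone H2B type 1",
                         E = "Histone H3.1", F = "Histone H4",
                         G = "Histone H2A type 1", H = "Histone H2B type 1"),
    dna_entity = "Nucleosomal DNA",
    partners = list(),
    extra_contacts = NULL,
    ptm_sites = NULL,
    resolution = 2.0,
    cutoff = 5.0
  )
}

#' Add a partner chain with planted contacts to a toy complex spec
#'
#' @param spec spec from [toy_complex_spec()].
#' @param name entity name of the partner.
#' @param length partner length in residues.
#' @param contacts data.frame with target_chain, target_resid, contact
#'   (logical; TRUE plants a contact, FALSE a near-miss) and optional dist.
#' @param hydrogen_decoy add a hydrogen atom at 3 A from the target for
#'   non-contact rows (exercises the heavy-atom rule).
#' @return updated spec.
#' @export
spec_add_partner <- function(spec, name, length = 20, contacts = NULL,
                             hydrogen_decoy = FALSE) {
  spec$partners[[length(spec$partners) + 1]] <-
    list(name = name, length = length, contacts = contacts,
         hydrogen_decoy = hydrogen_decoy)
  spec
}

#' Generate a toy nucleosome complex with planted contacts
#'
#' Writes a PDB file (and optionally an mmCIF twin with identical content)
#' plus a JSON truth sidecar listing every planted contact with its
#' interaction class. Same seed, same spec => byte-identical files.
#'
#' @param spec spec list from [toy_complex_spec()] /
#'   [spec_add_partner()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param write_cif also emit the mmCIF dialect.
#' @return list: structure, pdb_path, cif_path (or NA), truth_path, truth.
#' @export
generate_toy_complex <- function(spec, dir = tempdir(), name = "toy_complex",
                                 write_cif = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (try in seq_len(20)) {
    built <- .build_toy_complex(spec, jitter_try = try)
    verified <- .verify_planted(built, spec$cutoff)
    if (verified) break
    if (try == 20) stop("infeasible toy-complex spec: planted geometry ",
                        "could not be realized in 20 attempts")
  }
  st <- built$structure
  st$structure_id <- name
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  write_structure(st, pdb_path)
  cif_path <- NA_character_
  if (write_cif) {
    cif_path <- file.path(dir, paste0(name, ".cif"))
    .write_cif(st, cif_path)
  }
  truth <- list(structure_id = name, seed = spec$seed,
                cutoff = spec$cutoff,
                chain_roles = built$roles,
                contacts = built$truth_contacts,
                non_contacts = built$truth_noncontacts,
                class_counts = as.list(table(built$truth_contacts$class)))
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(structure = st, pdb_path = pdb_path, cif_path = cif_path,
       truth_path = truth_path, truth = truth)
}

.build_toy_complex <- function(spec, jitter_try = 1) {
  set.seed(spec$seed * 1000L + jitter_try)
  rows <- list()
  roles <- character(0)
  chain_index <- 0L
  add_chain <- function(chain_id, n_res, resnames, atom_name, element,
                        role) {
    y <- .CHAIN_ROW_SPACING * chain_index
    chain_index <<- chain_index + 1L
    roles[chain_id] <<- role
    rows[[chain_id]] <<- data.frame(
      chain_id = chain_id, residue_seq_id = seq_len(n_res),
      residue_name = resnames, atom_name = atom_name, element = element,
      x = .RESIDUE_SPACING * seq_len(n_res), y = y, z = 0,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (ch in names(spec$histone_entities)) {
    add_chain(ch, spec$histone_chain_length,
              rep("ALA", spec$histone_chain_length), "CA", "C", "histone")
  }
  dna_pat <- rep_len(c("DA", "DT", "DG", "DC"), spec$dna_length)
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
  add_chain("I", spec$dna_length, dna_pat, "P", "P", "dna")
  add_chain("J", spec$dna_length, rev(unname(comp[dna_pat])), "P", "P",
            "dna")
  partner_ids <- c("P", "Q", "R", "S", "T", "U", "V", "W")
  entity_names <- c(spec$histone_entities,
                    I = spec$dna_entity, J = spec$dna_entity)
  plant_rows <- list()
  for (k in seq_along(spec$partners)) {
    p <- spec$partners[[k]]
    pid <- partner_ids[k]
    add_chain(pid, p$length, rep("ALA", p$length), "CA", "C", "partner")
    entity_names[pid] <- p$name
    if (!is.null(p$contacts) && nrow(p$contacts)) {
      pc <- p$contacts
      pc$chain_b <- pid
      # probe residues: use the tail of the partner chain, one per plant
      pc$resid_b <- p$length - seq_len(nrow(pc)) + 1L
      pc$hydrogen_decoy <- p$hydrogen_decoy
      plant_rows[[length(plant_rows) + 1]] <- pc
    }
  }
  if (!is.null(spec$extra_contacts) && nrow(spec$extra_contacts)) {
    ec <- spec$extra_contacts
    names(ec)[names(ec) == "chain_a"] <- "target_chain"
    names(ec)[names(ec) == "resid_a"] <- "target_resid"
    ec$hydrogen_decoy <- FALSE
    plant_rows[[length(plant_rows) + 1]] <- ec
  }
  plants <- if (length(plant_rows)) {
    cols <- c("target_chain", "target_resid", "contact", "dist",
              "chain_b", "resid_b", "hydrogen_decoy")
    do.call(rbind, lapply(plant_rows, function(d) {
      if (is.null(d$dist)) d$dist <- NA_real_
      d[, cols]
    }))
  } else NULL

  atoms <- do.call(rbind, rows)
  decoys <- list()
  truth_contacts <- list()
  truth_noncontacts <- list()
  if (!is.null(plants)) {
    bkey <- paste(plants$chain_b, plants$resid_b)
    if (anyDuplicated(bkey)) {
      stop("infeasible spec: probe residue reused across plants")
    }
    if (any(bkey %in% paste(plants$target_chain, plants$target_resid))) {
      stop("infeasible spec: probe residue is also a plant anchor")
    }
    # orthogonal placement directions per anchor keep simultaneous plants
    # on one anchor farther apart than the cutoff
    dirs <- matrix(c(0, 0, 1, 0, 0, -1, 0, 1, 0, 0, -1, 0),
                   ncol = 3, byrow = TRUE)
    anchor_count <- integer(0)
    for (i in seq_len(nrow(plants))) {
      tc <- plants$target_chain[i]; tr <- plants$target_resid[i]
      akey <- paste(tc, tr)
      anchor_count[akey] <- (anchor_count[akey] %||na% 0L) + 1L
      if (anchor_count[akey] > 4) {
        stop("infeasible spec: more than 4 plants on one anchor")
      }
      a_idx <- which(atoms$chain_id == tc & atoms$residue_seq_id == tr)
      if (!length(a_idx)) stop("plant anchor not found: chain ", tc,
                               " residue ", tr)
      d <- plants$dist[i]
      if (is.na(d)) {
        d <- if (isTRUE(plants$contact[i])) {
          stats::runif(1, spec$cutoff - 0.5, spec$cutoff - 0.1)
        } else {
          stats::runif(1, spec$cutoff + 0.1, spec$cutoff + 2.0)
        }
      }
      dirv <- dirs[anchor_count[akey], ]
      b_idx <- which(atoms$chain_id == plants$chain_b[i] &
                       atoms$residue_seq_id == plants$resid_b[i])
      atoms$x[b_idx] <- atoms$x[a_idx[1]] + d * dirv[1]
      atoms$y[b_idx] <- atoms$y[a_idx[1]] + d * dirv[2]
      atoms$z[b_idx] <- atoms$z[a_idx[1]] + d * dirv[3]
      rec <- data.frame(chain_a = tc, resid_a = tr,
                        chain_b = plants$chain_b[i],
                        resid_b = plants$resid_b[i],
                        dist = d,
                        class = .class_from_roles(roles[[tc]],
                                                  roles[[plants$chain_b[i]]]),
                        stringsAsFactors = FALSE)
      if (isTRUE(plants$contact[i])) {
        truth_contacts[[length(truth_contacts) + 1]] <- rec
      } else {
        truth_noncontacts[[length(truth_noncontacts) + 1]] <- rec
        if (isTRUE(plants$hydrogen_decoy[i])) {
          decoys[[length(decoys) + 1]] <- data.frame(
            chain_id = plants$chain_b[i],
            residue_seq_id = plants$resid_b[i],
            residue_name = "ALA", atom_name = "H", element = "H",
            x = atoms$x[a_idx[1]] + 3 * dirv[1],
            y = atoms$y[a_idx[1]] + 3 * dirv[2],
            z = atoms$z[a_idx[1]] + 3 * dirv[3],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!is.null(spec$ptm_sites) && nrow(spec$ptm_sites)) {
    for (i in seq_len(nrow(spec$ptm_sites))) {
      sel <- atoms$chain_id == spec$ptm_sites$chain[i] &
        atoms$residue_seq_id == spec$ptm_sites$resid[i]
      atoms$residue_name[sel] <- spec$ptm_sites$resname[i]
    }
  }
  if (length(decoys)) atoms <- rbind(atoms, do.call(rbind, decoys))
  st <- structure_from_atoms(atoms, entity_names = entity_names,
                             structure_id = "toy", resolution =
                               spec$resolution)
  canon <- function(lst) {
    if (!length(lst)) {
      return(data.frame(chain_a = character(0), resid_a = integer(0),
                        chain_b = character(0), resid_b = integer(0),
                        dist = numeric(0), class = character(0),
                        stringsAsFactors = FALSE))
    }
    d <- do.call(rbind, lst)
    swap <- d$chain_a > d$chain_b
    tmp_c <- d$chain_a[swap]; d$chain_a[swap] <- d$chain_b[swap]
    d$chain_b[swap] <- tmp_c
    tmp_r <- d$resid_a[swap]; d$resid_a[swap] <- d$resid_b[swap]
    d$resid_b[swap] <- tmp_r
    d[order(d$chain_a, d$resid_a, d$chain_b, d$resid_b), , drop = FALSE]
  }
  list(structure = st, roles = as.list(roles),
       truth_contacts = canon(truth_contacts),
       truth_noncontacts = canon(truth_noncontacts))
}

# all-pairs verification that the realized geometry plants exactly the
# intended contact set (heavy atoms, inclusive cutoff)
.verify_planted <- function(built, cutoff) {
  found <- .allpairs_residue_contacts(built$structure, cutoff)
  fk <- paste(found$chain_a, found$resid_a, found$chain_b, found$resid_b)
  tk <- paste(built$truth_contacts$chain_a, built$truth_contacts$resid_a,
              built$truth_contacts$chain_b, built$truth_contacts$resid_b)
  setequal(fk, tk)
}

# brute-force O(n^2) inter-chain residue contacts (generator-side check)
.allpairs_residue_contacts <- function(structure, cutoff) {
  at <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  n <- nrow(at)
  if (n < 2) {
    return(data.frame(chain_a = character(0), resid_a = integer(0),
                      chain_b = character(0), resid_b = integer(0)))
  }
  d2 <- as.matrix(stats::dist(cbind(at$x, at$y, at$z)))^2
  hit <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(chain_a = character(0), resid_a = integer(0),
                      chain_b = character(0), resid_b = integer(0)))
  }
  i <- hit[, 1]; j <- hit[, 2]
  keep <- at$chain_id[i] != at$chain_id[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) {
    return(data.frame(chain_a = character(0), resid_a = integer(0),
                      chain_b = character(0), resid_b = integer(0)))
  }
  swap <- (at$chain_id[i] > at$chain_id[j]) |
    (at$chain_id[i] == at$chain_id[j] &
       at$residue_seq_id[i] > at$residue_seq_id[j])
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  out <- unique(data.frame(chain_a = at$chain_id[i],
                           resid_a = at$residue_seq_id[i],
                           chain_b = at$chain_id[j],
                           resid_b = at$residue_seq_id[j],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# minimal mmCIF writer (atom_site + entity description blocks)
.write_cif <- function(structure, path) {
  at <- structure$atoms
  ch <- structure$chains
  lines <- c(paste0("data_", structure$structure_id))
  if (!is.na(structure$resolution)) {
    lines <- c(lines, sprintf("_refine.ls_d_res_high %.2f",
                              structure$resolution))
  }
  have <- !is.na(ch$entity_name)
  if (any(have)) {
    ents <- unique(ch$entity_name[have])
    lines <- c(lines, "loop_", "_entity.id", "_entity.pdbx_description",
               vapply(seq_along(ents), function(i)
                 sprintf("%d '%s'", i, ents[i]), character(1)))
    lines <- c(lines, "loop_", "_entity_poly.entity_id",
               "_entity_poly.pdbx_strand_id",
               vapply(seq_along(ents), function(i) {
                 ids <- ch$chain_id[have & ch$entity_name == ents[i]]
                 sprintf("%d '%s'", i, paste(ids, collapse = ","))
               }, character(1)))
  }
  ent_of <- function(chain) {
    nm <- ch$entity_name[match(chain, ch$chain_id)]
    if (is.na(nm)) 0L else match(nm, unique(ch$entity_name[have]))
  }
  lines <- c(lines, "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
  rec <- ifelse(at$residue_name %in% .AA3 |
                  .is_dna_component(at$residue_name) |
                  .is_rna_component(at$residue_name), "ATOM", "HETATM")
  lines <- c(lines, sprintf(
    "%s %d %s %s . %s %s %d %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    rec, seq_len(nrow(at)), at$element, at$atom_name, at$residue_name,
    at$chain_id, vapply(at$chain_id, ent_of, integer(1)),
    at$residue_seq_id, at$x, at$y, at$z, 1, 0, at$residue_seq_id,
    at$residue_name, at$chain_id, at$atom_name))
  lines <- c(lines, "#")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random multi-chain point-cloud structure
#'
#' Uniform random heavy/hydrogen atoms in a cubic box, partitioned into
#' chains and residues: used to exercise contact detection against the
#' all-pairs oracle at scale.
#'
#' @param n_atoms total atom count.
#' @param n_chains number of chains.
#' @param box_size box edge in Angstrom.
#' @param hydrogen_fraction fraction of hydrogen atoms.
#' @param seed integer seed.
#' @return a `histone_structure`.
#' @export
generate_random_structure <- function(n_atoms = 500, n_chains = 4,
                                      box_size = 40,
                                      hydrogen_fraction = 0.1, seed = 1) {
  set.seed(seed)
  chain_ids <- LETTERS[seq_len(n_chains)]
  chain <- sort(sample(chain_ids, n_atoms, replace = TRUE))
  resno <- unlist(lapply(split(seq_len(n_atoms), chain), function(ix)
    rep(seq_len(ceiling(length(ix) / 3)), each = 3)[seq_along(ix)]))
  is_h <- stats::runif(n_atoms) < hydrogen_fraction
  atoms <- data.frame(
    chain_id = chain, residue_seq_id = as.integer(resno),
    residue_name = "ALA",
    atom_name = ifelse(is_h, "H", "CA"),
    element = ifelse(is_h, "H", "C"),
    x = stats::runif(n_atoms, 0, box_size),
    y = stats::runif(n_atoms, 0, box_size),
    z = stats::runif(n_atoms, 0, box_size),
    stringsAsFactors = FALSE)
  structure_from_atoms(atoms, structure_id = paste0("random_", seed))
}

# ---- mutation tables --------------------------------------------------------

# charge reversals: comfortably above every disruptive threshold under the
# surrogate score
.HIGH_IMPACT_SUBS <- data.frame(
  wt = c("R", "K", "E", "D", "R", "K"),
  mut = c("E", "D", "K", "R", "D", "E"),
  stringsAsFactors = FALSE)
.LOW_IMPACT_SUBS <- data.frame(
  wt = c("L", "S", "V", "I", "T", "A"),
  mut = c("I", "T", "I", "V", "S", "G"),
  stringsAsFactors = FALSE)

#' Default synthetic mutation-table specification
#'
#' Plants, with known counts: pass-all singleton missense records, recurrent
#' mutations (>= 3 samples) on interface positions with designed-disruptive
#' or designed-neutral substitutions, targeted-sequencing records, somatic-
#' unmatched records, nonsense records, dbSNP-known records, and records in
#' high-burden samples (including a decoy recurrent mutation that the TMB
#' filter must remove).
#'
#' @param seed integer seed.
#' @return spec list for [generate_mutation_table()].
#' @export
mutation_table_spec <- function(seed = 1) {
  interface_map <- data.frame(
    gene = c("H3C1", "H3C1", "H4C1", "H4C1", "H2AC11", "H2BC11",
             "H3C1", "H4C1", "H2AC11"),
    pos = c(27, 36, 31, 77, 29, 49, 96, 45, 56),
    class = c("HPI", "HHI", "HDI", "HHI", "HDI", "HPI", "HHI", "HDI",
              "HPI"),
    stringsAsFactors = FALSE)
  list(
    seed = seed,
    genes = c("H3C1", "H4C1", "H2AC11", "H2BC11", "H1-4"),
    interface_map = interface_map,
    n_pass = 40,
    recurrent = list(n = 7, samples_each = 3,
                     disruptive = c(HDI = 1, HHI = 1, HPI = 1)),
    n_targeted = 3,
    n_unmatched = 2,
    n_nonsense = 2,
    n_dbsnp = 3,
    high_tmb_decoy = TRUE,
    cancer_types = c("Breast Cancer", "Bladder Cancer",
                     "Non-Small Cell Lung Cancer", "Melanoma",
                     "Colorectal Cancer")
  )
}

#' Generate a synthetic mutation table with a truth sidecar
#'
#' Emits a MAF-like TSV, a residue-network JSON consistent with the planted
#' interface positions, and a JSON truth sidecar stating the expected
#' combined-set size, refined-set size, recurrent mutation keys, per-class
#' interface-mapping counts and designed-disruptive keys.
#'
#' @param spec spec list from [mutation_table_spec()].
#' @param dir output directory.
#' @param name file stem.
#' @return list: tsv_path, network_path, truth_path, truth.
#' @export
generate_mutation_table <- function(spec, dir = tempdir(),
                                    name = "mutations") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n_recurrent <- spec$recurrent$n
  n_disr <- sum(spec$recurrent$disruptive)
  if (n_disr > n_recurrent) stop("contradictory spec: more disruptive ",
                                 "mutations than recurrent mutations")
  if (n_recurrent > nrow(spec$interface_map)) {
    stop("contradictory spec: more recurrent mutations than interface ",
         "positions")
  }
  samples_each <- spec$recurrent$samples_each
  n_samples <- spec$n_pass + 20
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  tmb <- round(stats::runif(n_samples, 2, 8), 2)
  high_ids <- sprintf("T%03d", 1:4)
  high_tmb <- round(stats::runif(4, 12, 30), 2)

  surrogate <- ddg_surrogate_predictor()
  rows <- list()
  add <- function(gene, wt, pos, mut, sample, vclass = "missense",
                  seqtype = "wxs", somatic = "matched", tmb_val, dbsnp = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene = gene, protein_change = paste0(wt, pos, mut),
      sample_id = sample,
      cancer_type = sample(spec$cancer_types, 1),
      variant_class = vclass, sequencing_type = seqtype,
      somatic_status = somatic, sample_tmb = tmb_val, in_dbsnp = dbsnp,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  # recurrent mutations on interface positions; first the designed-
  # disruptive ones per class, then designed-neutral ones
  imap <- spec$interface_map
  recurrent_keys <- character(0)
  disruptive_keys <- list(HDI = character(0), HHI = character(0),
                          HPI = character(0))
  used_rows <- integer(0)
  pick_row <- function(cls) {
    avail <- setdiff(which(imap$class == cls), used_rows)
    if (!length(avail)) stop("contradictory spec: not enough interface ",
                             "positions of class ", cls)
    avail[1]
  }
  slot <- 0L
  recurrent_rows <- integer(0)
  for (cls in names(spec$recurrent$disruptive)) {
    for (i in seq_len(spec$recurrent$disruptive[[cls]])) {
      r <- pick_row(cls); used_rows <- c(used_rows, r)
      recurrent_rows <- c(recurrent_rows, r)
      slot <- slot + 1L
      sub <- .HIGH_IMPACT_SUBS[(slot - 1L) %% nrow(.HIGH_IMPACT_SUBS) + 1L, ]
      mode <- if (cls == "HDI") "protein-dna" else "protein-protein"
      thr <- c(HDI = 1.0, HHI = 1.5, HPI = 1.5)[[cls]]
      val <- surrogate(NULL, NULL, imap$pos[r], sub$wt, sub$mut, mode)
      if (val < thr + 0.3) stop("designed-disruptive substitution too weak")
      key <- paste0(imap$gene[r], ":", sub$wt, imap$pos[r], sub$mut)
      recurrent_keys <- c(recurrent_keys, key)
      disruptive_keys[[cls]] <- c(disruptive_keys[[cls]], key)
      carriers <- sample(sample_ids, samples_each)
      for (s in carriers) {
        add(imap$gene[r], sub$wt, imap$pos[r], sub$mut, s,
            tmb_val = tmb[match(s, sample_ids)])
      }
    }
  }
  n_neutral <- n_recurrent - n_disr
  for (i in seq_len(n_neutral)) {
    avail <- setdiff(seq_len(nrow(imap)), used_rows)
    r <- avail[1]; used_rows <- c(used_rows, r)
    recurrent_rows <- c(recurrent_rows, r)
    slot <- slot + 1L
    sub <- .LOW_IMPACT_SUBS[(slot - 1L) %% nrow(.LOW_IMPACT_SUBS) + 1L, ]
    mode <- if (imap$class[r] == "HDI") "protein-dna" else "protein-protein"
    thr <- c(HDI = 1.0, HHI = 1.5, HPI = 1.5)[[imap$class[r]]]
    val <- surrogate(NULL, NULL, imap$pos[r], sub$wt, sub$mut, mode)
    if (val > thr - 0.3) stop("designed-neutral substitution too strong")
    key <- paste0(imap$gene[r], ":", sub$wt, imap$pos[r], sub$mut)
    recurrent_keys <- c(recurrent_keys, key)
    carriers <- sample(sample_ids, samples_each)
    for (s in carriers) {
      add(imap$gene[r], sub$wt, imap$pos[r], sub$mut, s,
          tmb_val = tmb[match(s, sample_ids)])
    }
  }

  # pass-all singletons at non-interface positions (distinct keys)
  aa <- c("A", "V", "L", "I", "S", "T", "N", "Q", "R", "K", "E", "D", "G")
  for (i in seq_len(spec$n_pass)) {
    gene <- spec$genes[(i - 1L) %% length(spec$genes) + 1L]
    pos <- 100 + i
    wt <- aa[(i - 1L) %% length(aa) + 1L]
    mut <- aa[i %% length(aa) + 1L]
    if (mut == wt) mut <- "W"
    s <- sample_ids[(i - 1L) %% length(sample_ids) + 1L]
    add(gene, wt, pos, mut, s, tmb_val = tmb[match(s, sample_ids)])
  }
  # filtered classes
  for (i in seq_len(spec$n_targeted)) {
    add("H3C1", "A", 200 + i, "V", sample_ids[i], seqtype = "targeted",
        tmb_val = tmb[i])
  }
  for (i in seq_len(spec$n_unmatched)) {
    add("H4C1", "S", 210 + i, "N", sample_ids[i], somatic = "unmatched",
        tmb_val = tmb[i])
  }
  for (i in seq_len(spec$n_nonsense)) {
    add("H2AC11", "R", 220 + i, "*", sample_ids[i], vclass = "nonsense",
        tmb_val = tmb[i])
  }
  for (i in seq_len(spec$n_dbsnp)) {
    add("H2BC11", "T", 230 + i, "M", sample_ids[i], tmb_val = tmb[i],
        dbsnp = TRUE)
  }
  n_decoy_records <- 0L
  if (isTRUE(spec$high_tmb_decoy)) {
    # a would-be recurrent mutation carried only by high-burden samples
    for (s in high_ids[1:3]) {
      add("H1-4", "K", 85, "R", s, tmb_val = high_tmb[match(s, high_ids)])
    }
    n_decoy_records <- 3L
  }

  tab <- do.call(rbind, rows)
  tsv_path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # residue network consistent with the planted interface positions
  net <- .interface_map_network(imap)
  network_path <- file.path(dir, paste0(name, ".network.json"))
  write_network_json(net, network_path)

  # dbSNP-known records pass the combined filters; they fall in the refined
  # stage only
  combined_n <- n_recurrent * samples_each + spec$n_pass + spec$n_dbsnp +
    n_decoy_records
  mapped_counts <- vapply(c("HDI", "HHI", "HPI"), function(cls)
    sum(imap$class[recurrent_rows] == cls), integer(1))
  truth <- list(
    n_raw = nrow(tab),
    combined_n_records = combined_n,
    refined_n_records = n_recurrent * samples_each,
    refined_n_mutations = n_recurrent,
    recurrent_keys = sort(recurrent_keys),
    mapped_counts = as.list(mapped_counts),
    disruptive_keys = disruptive_keys,
    seed = spec$seed)
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(tsv_path = tsv_path, network_path = network_path,
       truth_path = truth_path, truth = truth)
}

# one residue-level edge of the stated class per planted interface position
.interface_map_network <- function(imap) {
  nodes <- list(); edges <- list()
  counterpart <- c(HDI = "DNA:I.%d", HHI = "H4C1:%d", HPI = "PARTNER:%d")
  counter_class <- c(HDI = "dna", HHI = "histone", HPI = "partner")
  for (i in seq_len(nrow(imap))) {
    a <- paste0(imap$gene[i], ":", imap$pos[i])
    b <- sprintf(counterpart[[imap$class[i]]], 1000 + i)
    nodes[[length(nodes) + 1]] <- data.frame(
      node_id = c(a, b),
      node_class = c("histone", counter_class[[imap$class[i]]]),
      histone_type = NA_character_, organism = NA_character_,
      stringsAsFactors = FALSE)
    edges[[length(edges) + 1]] <- data.frame(
      node_a = a, node_b = b, interaction_class = imap$class[i],
      stringsAsFactors = FALSE)
  }
  nd <- do.call(rbind, nodes)
  nd <- nd[!duplicated(nd$node_id), , drop = FALSE]
  ed <- do.call(rbind, edges)
  ed$evidence <- replicate(nrow(ed), "structural:synthetic",
                           simplify = FALSE)
  hinet(nd, ed, granularity = "residue", provenance = "structural")
}

# ---- edge lists and graphs --------------------------------------------------

#' Generate protein-level edge lists with controlled overlap
#'
#' Emits structural / crosslink / highthroughput partner edge lists whose
#' pairwise partner overlap equals `round(n_partners * overlap)` (a shared
#' partner pool), each partner linked to one histone node.
#'
#' @param n_partners partners per evidence source.
#' @param overlap shared fraction in [0, 1].
#' @param seed integer seed.
#' @param dir optional output directory; when given, three TSVs and a truth
#'   JSON are written.
#' @return list of three edge data.frames (structural, crosslink,
#'   highthroughput) plus `truth` (and paths when written).
#' @export
generate_edge_lists <- function(n_partners = 100, overlap = 0.3, seed = 1,
                                dir = NULL) {
  stopifnot(overlap >= 0, overlap <= 1)
  set.seed(seed)
  histones <- c("H3", "H4", "H2A", "H2B", "H1")
  s <- round(n_partners * overlap)
  shared <- sprintf("SHARED%04d", seq_len(s))
  mk <- function(tag) {
    own <- if (n_partners - s > 0) {
      sprintf("%s%04d", tag, seq_len(n_partners - s))
    } else character(0)
    partners <- c(shared, own)
    data.frame(node_a = sample(histones, length(partners), replace = TRUE),
               node_b = partners,
               class_a = "histone", class_b = "partner",
               stringsAsFactors = FALSE)
  }
  out <- list(structural = mk("STR"), crosslink = mk("XL"),
              highthroughput = mk("HT"))
  truth <- list(n_partners = n_partners, overlap = overlap,
                shared_count = s, seed = seed)
  out$truth <- truth
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("structural", "crosslink", "highthroughput")) {
      p <- file.path(dir, paste0("edges_", nm, ".tsv"))
      utils::write.table(out[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out[[paste0(nm, "_path")]] <- p
    }
    tp <- file.path(dir, "edges.truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
    out$truth_path <- tp
  }
  out
}

#' Generate a preferential-attachment graph
#'
#' Barabasi-Albert growth from `m` unconnected seed nodes: each new node
#' attaches to `m` distinct existing nodes with probability proportional to
#' degree, giving exactly `m * (n - m)` edges. While any existing node still
#' has degree below `m`, one attachment slot per step is spent on the most
#' deficient node (seed-graph regularization), which guarantees minimum
#' degree `m` without changing the edge count or the asymptotic attachment
#' kernel.
#'
#' @param n node count.
#' @param m attachment count per new node (n > m >= 1).
#' @param seed integer seed.
#' @return two-column edge data.frame (node_a, node_b) with node names
#'   "n0001"...
#' @export
generate_scalefree_graph <- function(n, m, seed = 1) {
  stopifnot(n > m, m >= 1)
  set.seed(seed)
  deg <- integer(n)
  ea <- integer(m * (n - m)); eb <- integer(m * (n - m))
  k <- 0L
  repeated <- integer(0)
  for (v in (m + 1L):n) {
    existing <- seq_len(v - 1L)
    tgt <- integer(0)
    deficient <- existing[deg[existing] < m]
    if (length(deficient)) {
      tgt <- deficient[which.min(deg[deficient])]
    }
    while (length(tgt) < m) {
      pool <- c(repeated, existing)  # uniform term keeps new nodes reachable
      cand <- pool[sample.int(length(pool), 1L)]
      if (!(cand %in% tgt)) tgt <- c(tgt, cand)
    }
    for (t in tgt) {
      k <- k + 1L
      ea[k] <- v; eb[k] <- t
      deg[v] <- deg[v] + 1L; deg[t] <- deg[t] + 1L
      repeated <- c(repeated, v, t)
    }
  }
  data.frame(node_a = sprintf("n%04d", ea), node_b = sprintf("n%04d", eb),
             stringsAsFactors = FALSE)
}
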