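# Nucleosome-partner binding modes, representative-structure selection and
# binding hotspots on the histone octamer (consensus coordinates) and on
# nucleosomal/linker DNA (base-pair coordinates relative to the dyad).

#' Build per-(structure, partner) complex metadata
#'
#' Summarizes a parsed nucleosome complex for representative selection:
#' core-histone chain inventory, number of DNA base pairs without any
#' heavy-atom contact to the octamer, partner lengths and interface residue
#' sets.
#'
#' @param structure a `histone_structure`.
#' @param annotations chain annotations from [classify_chains()].
#' @param edges interface edge table from [extract_interfaces()] for this
#'   structure.
#' @param has_mutations logical flag (mutant constructs), default FALSE.
#' @param cutoff contact cutoff used for the lost-base-pair check.
#' @return data.frame, one row per partner molecule.
#' @export
complex_metadata <- function(structure, annotations, edges,
                             has_mutations = FALSE, cutoff = 5.0) {
  core <- annotations$histone_type %in% c("H2A", "H2B", "H3", "H4")
  n_core <- sum(core, na.rm = TRUE)
  dna_chains <- annotations$chain_id[annotations$role == "dna"]
  n_lost <- if (length(dna_chains)) {
    .lost_base_pairs(structure, annotations, cutoff)
  } else 0L
  partners <- unique(annotations$mol_id[annotations$role == "partner"])
  if (!length(partners)) {
    return(data.frame(structure_id = character(0), partner_id = character(0),
                      resolution = numeric(0), has_mutations = logical(0),
                      partner_length = integer(0),
                      n_core_histone_chains = integer(0),
                      n_lost_bp = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(partners, function(p) {
    ch <- annotations$chain_id[annotations$mol_id == p &
                                 annotations$role == "partner"]
    at <- structure$atoms[structure$atoms$chain_id %in% ch, ]
    plen <- max(vapply(ch, function(c1)
      length(unique(structure$atoms$residue_seq_id[
        structure$atoms$chain_id == c1])), integer(1)))
    iface <- .partner_interface_set(edges, p)
    data.frame(structure_id = structure$structure_id, partner_id = p,
               resolution = structure$resolution,
               has_mutations = has_mutations,
               partner_length = plen,
               n_core_histone_chains = n_core,
               n_lost_bp = n_lost, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$interface <- lapply(partners, function(p)
    .partner_interface_set(edges, p))
  rownames(out) <- NULL
  out
}

# interface positions contacted by a partner (histone consensus-free key:
# "mol:pos" on the nucleosome side plus DNA nucleotides)
.partner_interface_set <- function(edges, partner) {
  sub <- edges[(edges$class %in% c("HPI") & edges$mol_b == partner) |
                 (edges$class == "DPI" & edges$mol_a == partner), ,
               drop = FALSE]
  hp <- sub[sub$class == "HPI", , drop = FALSE]
  dp <- sub[sub$class == "DPI", , drop = FALSE]
  pos_h <- ifelse(is.na(hp$seq_pos_a), hp$resid_a, hp$seq_pos_a)
  sort(unique(c(paste0(hp$mol_a, ":", pos_h),
                paste0("DNA:", dp$chain_b, ".", dp$resid_b))))
}

# base pairs of the (paired) DNA duplex with no histone contact within cutoff
.lost_base_pairs <- function(structure, annotations, cutoff = 5.0) {
  dna_chains <- annotations$chain_id[annotations$role == "dna"]
  his_chains <- annotations$chain_id[annotations$role == "histone"]
  if (length(dna_chains) < 1 || !length(his_chains)) return(0L)
  sub <- prune_chains(structure, c(dna_chains, his_chains))
  contacts <- suppressWarnings(find_contacts(sub, cutoff))
  idx <- .dna_strand_index(structure, dna_chains)
  touched <- logical(max(idx$bp))
  hd <- contacts[(contacts$chain_a %in% dna_chains &
                    contacts$chain_b %in% his_chains) |
                   (contacts$chain_b %in% dna_chains &
                      contacts$chain_a %in% his_chains), , drop = FALSE]
  if (nrow(hd)) {
    dch <- ifelse(hd$chain_a %in% dna_chains, hd$chain_a, hd$chain_b)
    dres <- ifelse(hd$chain_a %in% dna_chains, hd$resid_a, hd$resid_b)
    hit <- idx$bp[match(paste(dch, dres), paste(idx$chain_id, idx$resid))]
    touched[stats::na.omit(hit)] <- TRUE
  }
  sum(!touched)
}

# index DNA strands: strand I keeps its 5'->3' order (bp = index), strand II
# pairs by reverse-complement indexing (bp = L + 1 - index)
.dna_strand_index <- function(structure, dna_chains, tol = 4L) {
  stopifnot(length(dna_chains) >= 1)
  per_chain <- lapply(dna_chains, function(ch) {
    res <- unique(structure$atoms$residue_seq_id[
      structure$atoms$chain_id == ch])
    data.frame(chain_id = ch, resid = sort(res),
               idx = seq_along(res), stringsAsFactors = FALSE)
  })
  L <- nrow(per_chain[[1]])
  if (length(per_chain) >= 2) {
    L2 <- nrow(per_chain[[2]])
    if (abs(L - L2) > tol) {
      stop("DNA strand length mismatch beyond tolerance: ", L, " vs ", L2)
    }
  }
  out <- list()
  out[[1]] <- transform(per_chain[[1]], bp = idx)
  if (length(per_chain) >= 2) {
    out[[2]] <- transform(per_chain[[2]], bp = L + 1L - per_chain[[2]]$idx)
  }
  idx <- do.call(rbind, out)
  idx$bp <- pmax(1L, pmin(idx$bp, L))
  attr(idx, "length_bp") <- L
  idx
}

#' Select representative nucleosome complex structures
#'
#' Applies, in order: removal of subnucleosomal structures (fewer than
#' `core_min` of the 8 core-histone chains), removal of structures where more
#' than `lost_bp_max` base pairs of nucleosomal DNA lost atomic contact with
#' the octamer, removal of partners shorter than `min_partner_len` residues,
#' and per-partner redundancy collapse: structures whose interface-residue
#' Jaccard similarity meets `redundancy_jaccard` share a binding mode and
#' only the highest-resolution mutation-free member is kept; distinct binding
#' modes of one partner each keep one structure.
#'
#' @param metadata data.frame as produced by [complex_metadata()] (rows may
#'   span many structures); the `interface` list column holds interface
#'   position sets.
#' @param redundancy_jaccard Jaccard threshold for "identical binding mode".
#' @param core_min minimum core-histone chain count (default 7 of 8).
#' @param lost_bp_max maximum number of octamer-detached base pairs.
#' @param min_partner_len minimum partner length in residues.
#' @return the selected rows of `metadata`, with a `mode_index` column.
#' @export
select_representatives <- function(metadata, redundancy_jaccard = 0.8,
                                   core_min = 7, lost_bp_max = 20,
                                   min_partner_len = 10) {
  md <- metadata
  md <- md[md$n_core_histone_chains >= core_min, , drop = FALSE]
  md <- md[md$n_lost_bp <= lost_bp_max, , drop = FALSE]
  md <- md[md$partner_length >= min_partner_len, , drop = FALSE]
  if (!nrow(md)) { md$mode_index <- integer(0); return(md) }

  keep_rows <- integer(0)
  mode_index <- integer(0)
  for (p in unique(md$partner_id)) {
    rows <- which(md$partner_id == p)
    sets <- md$interface[rows]
    # single-linkage clusters under Jaccard >= threshold
    cl <- seq_along(rows)
    repeat {
      changed <- FALSE
      for (i in seq_along(rows)) for (j in seq_along(rows)) {
        if (cl[i] != cl[j] &&
            .jaccard(sets[[i]], sets[[j]]) >= redundancy_jaccard) {
          cl[cl == cl[j]] <- cl[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    m <- 0L
    for (c1 in unique(cl)) {
      m <- m + 1L
      members <- rows[cl == c1]
      if (length(members) > 1 && anyNA(md$resolution[members])) {
        stop("missing resolution on contested group: structure(s) ",
             paste(md$structure_id[members][is.na(md$resolution[members])],
                   collapse = ", "))
      }
      ord <- order(md$has_mutations[members], md$resolution[members],
                   md$structure_id[members])
      keep_rows <- c(keep_rows, members[ord[1]])
      mode_index <- c(mode_index, m)
    }
  }
  out <- md[keep_rows, , drop = FALSE]
  out$mode_index <- mode_index
  out <- out[order(out$partner_id, out$mode_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}

#' Classify partner binding modes
#'
#' A partner is `dna_only` when it has DNA contacts (DPIs) and no histone
#' contacts, `histone_only` in the opposite case, and `both` when it has
#' both. Partners present in `partner_ids` but without any contact are
#' labeled `none` with a warning and are excluded from mode statistics.
#'
#' @param edges interface edge table (one or more structures).
#' @param partner_ids optional character vector of partner molecules to
#'   label; defaults to the partners appearing in `edges`.
#' @return data.frame: structure_id, partner_id, mode.
#' @export
classify_binding_mode <- function(edges, partner_ids = NULL) {
  part_in_edges <- unique(c(edges$mol_b[edges$class == "HPI"],
                            edges$mol_a[edges$class == "DPI"]))
  if (is.null(partner_ids)) partner_ids <- part_in_edges
  rows <- lapply(partner_ids, function(p) {
    sub_h <- edges$class == "HPI" & edges$mol_b == p
    sub_d <- edges$class == "DPI" & edges$mol_a == p
    sid <- unique(edges$structure_id[sub_h | sub_d])
    mode <- if (any(sub_h) && any(sub_d)) "both"
            else if (any(sub_h)) "histone_only"
            else if (any(sub_d)) "dna_only"
            else "none"
    data.frame(structure_id = if (length(sid)) sid[1] else NA_character_,
               partner_id = p, mode = mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$mode == "none")) {
    warning(sum(out$mode == "none"),
            " partner(s) without contacts labeled 'none' and excluded ",
            "from mode statistics", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Binding-mode fractions
#' @param labels data.frame from [classify_binding_mode()].
#' @return named numeric vector over dna_only / histone_only / both,
#'   summing to 1 (partners labeled "none" excluded).
#' @export
binding_mode_fractions <- function(labels) {
  lab <- labels$mode[labels$mode != "none"]
  out <- c(dna_only = 0, histone_only = 0, both = 0)
  if (length(lab)) {
    tab <- table(factor(lab, levels = names(out)))
    out <- as.numeric(tab) / length(lab)
    names(out) <- c("dna_only", "histone_only", "both")
  }
  out
}

#' Read an aligned FASTA file
#' @param path aligned FASTA (rows padded with '-' gaps).
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aln), names(aln))
}

#' Map ungapped variant positions to consensus alignment columns
#'
#' The consensus position of residue `p` of a variant is the alignment
#' column holding that variant's p-th non-gap character. Residues in columns
#' where every other variant has a gap are flagged (`insertion_only`).
#'
#' @param positions data.frame with columns `variant` (alignment row name)
#'   and `position` (1-based ungapped coordinate).
#' @param alignment named character vector of aligned sequences (equal
#'   widths), e.g. from [read_alignment()].
#' @return the input with `consensus_position` and `insertion_only` added.
#' @export
map_to_consensus <- function(positions, alignment) {
  widths <- unique(nchar(alignment))
  if (length(widths) != 1) stop("alignment rows have unequal widths")
  colmaps <- lapply(alignment, function(s) {
    chars <- strsplit(s, "")[[1]]
    which(chars != "-")
  })
  gapmat <- do.call(rbind, lapply(alignment, function(s)
    strsplit(s, "")[[1]] == "-"))
  out <- positions
  out$consensus_position <- NA_integer_
  out$insertion_only <- NA
  for (i in seq_len(nrow(out))) {
    v <- as.character(out$variant[i])
    if (!v %in% names(colmaps)) {
      stop("variant '", v, "' missing from alignment")
    }
    p <- out$position[i]
    cm <- colmaps[[v]]
    if (is.na(p) || p < 1 || p > length(cm)) {
      stop("position ", p, " beyond aligned length of variant '", v, "'")
    }
    col <- cm[p]
    out$consensus_position[i] <- col
    others <- setdiff(rownames(gapmat), v)
    out$insertion_only[i] <- length(others) > 0 && all(gapmat[others, col])
  }
  out
}

#' Profile partner-binding hotspots on histone consensus positions
#'
#' For each consensus position of each histone type: the number of distinct
#' partner proteins (not chains) with at least one contact to that position
#' across the supplied structures, and the mean heavy-atom contact count over
#' the (structure, partner) pairs that touch the position. Untouched
#' positions are reported with zeros.
#'
#' @param edges interface edge table restricted to the representative
#'   structures (HPI rows are used).
#' @param alignments named list: histone type -> alignment (named character
#'   vector); variant names must match the `mol_a` molecule ids.
#' @return data.frame: histone_type, consensus_position, unique_partners,
#'   mean_contacts.
#' @export
profile_histone_hotspots <- function(edges, alignments) {
  hp <- edges[edges$class == "HPI", , drop = FALSE]
  out <- list()
  for (ht in names(alignments)) {
    aln <- alignments[[ht]]
    width <- unique(nchar(aln))[1]
    sub <- hp[!is.na(hp$histone_type_a) & hp$histone_type_a == ht, ,
              drop = FALSE]
    prof <- data.frame(histone_type = ht,
                       consensus_position = seq_len(width),
                       unique_partners = 0L, mean_contacts = 0,
                       stringsAsFactors = FALSE)
    if (nrow(sub)) {
      pos <- ifelse(is.na(sub$seq_pos_a), sub$resid_a, sub$seq_pos_a)
      mapped <- map_to_consensus(
        data.frame(variant = sub$mol_a, position = pos,
                   stringsAsFactors = FALSE), aln)
      sub$cpos <- mapped$consensus_position
      # per (structure, partner, position): summed atomic contacts
      agg <- stats::aggregate(
        n_atom_contacts ~ cpos + structure_id + mol_b, data = sub, FUN = sum)
      np <- tapply(agg$mol_b, agg$cpos, function(v) length(unique(v)))
      mc <- tapply(agg$n_atom_contacts, agg$cpos, mean)
      at <- as.integer(names(np))
      prof$unique_partners[match(at, prof$consensus_position)] <-
        as.integer(np)
      prof$mean_contacts[match(at, prof$consensus_position)] <-
        as.numeric(mc)
    }
    out[[ht]] <- prof
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Profile partner-binding hotspots on DNA base pairs
#'
#' Base pairs are indexed relative to the dyad (dyad = 0); a partner counts
#' for a base pair when it contacts either strand's nucleotide of that pair.
#' Superhelic locations are reported as bp / 10 rounded.
#'
#' @param edges interface edge table (DPI rows are used).
#' @param structures named list of `histone_structure` objects keyed by
#'   structure id (for strand indexing).
#' @param annotations_list named list of chain annotation tables keyed by
#'   structure id.
#' @param dyad_config optional named numeric vector structure id -> dyad bp
#'   index; defaults to the strand midpoint `ceiling(L / 2)`.
#' @return data.frame: bp (relative to dyad), shl, unique_partners,
#'   mean_contacts.
#' @export
profile_dna_hotspots <- function(edges, structures, annotations_list,
                                 dyad_config = NULL) {
  dp <- edges[edges$class == "DPI", , drop = FALSE]
  if (!nrow(dp)) {
    return(data.frame(bp = integer(0), shl = numeric(0),
                      unique_partners = integer(0),
                      mean_contacts = numeric(0)))
  }
  rows <- list()
  for (sid in unique(dp$structure_id)) {
    st <- structures[[sid]]
    ann <- annotations_list[[sid]]
    if (is.null(st) || is.null(ann)) {
      stop("structure or annotations missing for '", sid, "'")
    }
    dna_chains <- ann$chain_id[ann$role == "dna"]
    idx <- .dna_strand_index(st, dna_chains)
    L <- attr(idx, "length_bp")
    dyad <- if (!is.null(dyad_config) && sid %in% names(dyad_config)) {
      as.numeric(dyad_config[[sid]])
    } else ceiling(L / 2)
    sub <- dp[dp$structure_id == sid, , drop = FALSE]
    bp_abs <- idx$bp[match(paste(sub$chain_b, sub$resid_b),
                           paste(idx$chain_id, idx$resid))]
    ok <- !is.na(bp_abs)
    rows[[sid]] <- data.frame(structure_id = sid,
                              partner = sub$mol_a[ok],
                              bp = bp_abs[ok] - dyad,
                              n = sub$n_atom_contacts[ok],
                              stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  # a partner counts once per bp even when contacting both strands
  agg <- stats::aggregate(n ~ bp + structure_id + partner, data = all,
                          FUN = sum)
  np <- tapply(agg$partner, agg$bp, function(v) length(unique(v)))
  mc <- tapply(agg$n, agg$bp, mean)
  bp <- as.integer(names(np))
  out <- data.frame(bp = bp, shl = round(bp / 10),
                    unique_partners = as.integer(np),
                    mean_contacts = as.numeric(mc))
  out <- out[order(out$bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare binding interfaces across functional classes
#'
#' Per functional class of the binding partners: the union of contacted
#' histone consensus positions, with positions contacted by at least two
#' distinct partners flagged as shared. Structures absent from the
#' annotation table are grouped as "unclassified" with a warning.
#'
#' @param edges interface edge table for the selected structures (HPI rows).
#' @param alignments named list of alignments per histone type (see
#'   [profile_histone_hotspots()]).
#' @param functional_annotations data.frame (structure_id, class).
#' @return data.frame: class, histone_type, consensus_position, n_partners,
#'   shared.
#' @export
compare_modes_by_function <- function(edges, alignments,
                                      functional_annotations) {
  hp <- edges[edges$class == "HPI", , drop = FALSE]
  if (!nrow(hp)) {
    return(data.frame(class = character(0), histone_type = character(0),
                      consensus_position = integer(0),
                      n_partners = integer(0), shared = logical(0)))
  }
  cls <- functional_annotations$class[
    match(hp$structure_id, functional_annotations$structure_id)]
  if (anyNA(cls)) {
    warning("structure(s) without functional annotation grouped as ",
            "'unclassified'", call. = FALSE)
    cls[is.na(cls)] <- "unclassified"
  }
  hp$fclass <- cls
  out <- list()
  for (fc in unique(hp$fclass)) {
    sub <- hp[hp$fclass == fc, , drop = FALSE]
    sub <- sub[!is.na(sub$histone_type_a) &
                 sub$histone_type_a %in% names(alignments), , drop = FALSE]
    if (!nrow(sub)) next
    pos <- ifelse(is.na(sub$seq_pos_a), sub$resid_a, sub$seq_pos_a)
    parts <- lapply(unique(sub$histone_type_a), function(ht) {
      s2 <- sub[sub$histone_type_a == ht, , drop = FALSE]
      p2 <- ifelse(is.na(s2$seq_pos_a), s2$resid_a, s2$seq_pos_a)
      mapped <- map_to_consensus(
        data.frame(variant = s2$mol_a, position = p2,
                   stringsAsFactors = FALSE), alignments[[ht]])
      np <- tapply(s2$mol_b, mapped$consensus_position,
                   function(v) length(unique(v)))
      data.frame(class = fc, histone_type = ht,
                 consensus_position = as.integer(names(np)),
                 n_partners = as.integer(np),
                 shared = as.integer(np) >= 2L,
                 stringsAsFactors = FALSE)
    })
    out[[fc]] <- do.call(rbind, parts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a hotspot profile to TSV
#' @param profile data.frame from [profile_histone_hotspots()] or
#'   [profile_dna_hotspots()].
#' @param path output path.
#' @param axis "histone_consensus" or "dna_bp".
#' @return `path`, invisibly.
#' @export
write_hotspot_tsv <- function(profile, path,
                              axis = c("histone_consensus", "dna_bp")) {
  axis <- match.arg(axis)
  profile$axis <- axis
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
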