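# Heavy-atom contact detection and interaction-class assignment.
#
# A residue pair on different chains is in contact when any pair of heavy
# atoms lies within the cutoff (inclusive; default 5 A). Detection uses a
# uniform spatial grid with cell size = cutoff, so only atoms in adjacent
# cells are compared; the result is identical to the all-pairs computation.

#' Find inter-chain residue contacts
#'
#' @param structure a `histone_structure`.
#' @param cutoff contact distance in Angstrom (inclusive comparison).
#' @return data.frame of contact pairs: chain_a, resid_a, resname_a, chain_b,
#'   resid_b, resname_b, min_distance, atom_contact_count. Pairs are stored
#'   canonically (a < b by chain, then residue number); intra-chain pairs are
#'   never reported and only heavy atoms enter the distance computation.
#' @export
find_contacts <- function(structure, cutoff = 5.0) {
  stopifnot(inherits(structure, "histone_structure"), cutoff > 0)
  at <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  empty <- data.frame(chain_a = character(0), resid_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resid_b = integer(0), resname_b = character(0),
                      min_distance = numeric(0),
                      atom_contact_count = integer(0),
                      stringsAsFactors = FALSE)
  if (length(unique(at$chain_id)) < 2) {
    warning("structure has fewer than two chains with heavy atoms; ",
            "no inter-chain contacts", call. = FALSE)
    return(empty)
  }
  coords <- cbind(at$x, at$y, at$z)
  pairs <- .grid_atom_pairs(coords, cutoff)
  if (!nrow(pairs)) return(empty)
  i <- pairs[, 1]; j <- pairs[, 2]
  inter <- at$chain_id[i] != at$chain_id[j]
  i <- i[inter]; j <- j[inter]; d <- sqrt(pairs[inter, 3])
  if (!length(i)) return(empty)

  # canonical residue-pair orientation: (chain, resid) a before b
  swap <- (at$chain_id[i] > at$chain_id[j]) |
    (at$chain_id[i] == at$chain_id[j] &
       at$residue_seq_id[i] > at$residue_seq_id[j])
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp

  key <- paste(at$chain_id[i], at$residue_seq_id[i],
               at$chain_id[j], at$residue_seq_id[j], sep = "\r")
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- data.frame(
    chain_a = at$chain_id[i][first],
    resid_a = at$residue_seq_id[i][first],
    resname_a = at$residue_name[i][first],
    chain_b = at$chain_id[j][first],
    resid_b = at$residue_seq_id[j][first],
    resname_b = at$residue_name[j][first],
    min_distance = as.numeric(tapply(d, grp, min)),
    atom_contact_count = as.integer(tapply(d, grp, length)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chain_a, out$resid_a, out$chain_b, out$resid_b), ]
  rownames(out) <- NULL
  out
}

# All atom pairs within cutoff, via a uniform grid (cell size = cutoff).
# Returns a matrix with columns i, j, squared distance.
.grid_atom_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  cell <- floor(coords / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  # decode bucket keys back to integer cell coordinates
  kmat <- matrix(as.integer(unlist(strsplit(names(buckets), " ",
                                            fixed = TRUE))),
                 ncol = 3, byrow = TRUE)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_along(buckets)) assign(names(buckets)[b], b, envir = index)
  half_offsets <- .half_space_offsets()
  cut2 <- cutoff^2
  acc <- list()
  nacc <- 0L
  push <- function(m) {
    nacc <<- nacc + 1L
    acc[[nacc]] <<- m
  }
  for (b in seq_along(buckets)) {
    I <- buckets[[b]]
    if (length(I) > 1) {
      cmb <- utils::combn(I, 2)
      d2 <- rowSums((coords[cmb[1, ], , drop = FALSE] -
                       coords[cmb[2, ], , drop = FALSE])^2)
      hit <- d2 <= cut2
      if (any(hit)) push(cbind(cmb[1, hit], cmb[2, hit], d2[hit]))
    }
    for (o in seq_len(nrow(half_offsets))) {
      nb_key <- paste(kmat[b, 1] + half_offsets[o, 1],
                      kmat[b, 2] + half_offsets[o, 2],
                      kmat[b, 3] + half_offsets[o, 3])
      nb <- index[[nb_key]]
      if (is.null(nb)) next
      J <- buckets[[nb]]
      dx <- outer(coords[I, 1], coords[J, 1], "-")
      dy <- outer(coords[I, 2], coords[J, 2], "-")
      dz <- outer(coords[I, 3], coords[J, 3], "-")
      d2 <- dx^2 + dy^2 + dz^2
      hit <- which(d2 <= cut2, arr.ind = TRUE)
      if (nrow(hit)) {
        push(cbind(I[hit[, 1]], J[hit[, 2]], d2[hit]))
      }
    }
  }
  if (!nacc) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, acc[seq_len(nacc)])
}

# 13 lexicographically-positive neighbor offsets: each unordered cell pair is
# visited exactly once.
.half_space_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  keep <- g$dx > 0 | (g$dx == 0 & g$dy > 0) |
    (g$dx == 0 & g$dy == 0 & g$dz > 0)
  as.matrix(g[keep, ])
}

#' Classify one contact into an interaction class
#'
#' Histone-histone contacts are HHIs, histone-DNA HDIs, histone-partner HPIs
#' and partner-DNA DPIs. Partner-partner (and DNA-DNA) contacts are labeled
#' `PP` (`DD`); they are retained in contact tables but excluded from the
#' four-class networks.
#'
#' @param contact one row of a [find_contacts()] table (or any list with
#'   chain_a / chain_b).
#' @param annotations chain annotations from [classify_chains()].
#' @return single character class.
#' @export
classify_contact <- function(contact, annotations) {
  ra <- annotations$role[match(contact$chain_a, annotations$chain_id)]
  rb <- annotations$role[match(contact$chain_b, annotations$chain_id)]
  if (any(is.na(c(ra, rb)))) {
    stop("unannotated chain(s): ",
         paste(unique(c(contact$chain_a, contact$chain_b)[is.na(c(ra, rb))]),
               collapse = ", "))
  }
  .class_from_roles(ra, rb)
}

.class_from_roles <- function(ra, rb) {
  pair <- paste(sort(c(ra, rb)), collapse = "+")
  switch(pair,
         "histone+histone" = "HHI",
         "dna+histone" = "HDI",
         "histone+partner" = "HPI",
         "dna+partner" = "DPI",
         "partner+partner" = "PP",
         "dna+dna" = "DD",
         "other")
}

#' Extract classified residue-level interfaces from a structure
#'
#' Runs contact detection, classifies every inter-chain residue pair,
#' orients edges (histone side first, then partner, then DNA), attaches
#' sequence positions and PTM types, and collects per-class interface
#' residue sets.
#'
#' @param structure a `histone_structure` (ideally after
#'   [apply_residue_mapping()]).
#' @param annotations chain annotations from [classify_chains()].
#' @param ptm_map named vector component id -> PTM type
#'   (default [default_ptm_map()]).
#' @param cutoff contact cutoff in Angstrom.
#' @param organism optional organism label carried onto edges.
#' @return list with `edges` (classified residue-level edge table, evidence =
#'   structure id) and `interface_residues` (per-class residue tables).
#' @export
extract_interfaces <- function(structure, annotations,
                               ptm_map = default_ptm_map(), cutoff = 5.0,
                               organism = NA_character_) {
  contacts <- find_contacts(structure, cutoff)
  ann <- annotations
  need <- setdiff(unique(c(contacts$chain_a, contacts$chain_b)), ann$chain_id)
  if (length(need)) stop("unannotated chain(s): ", paste(need, collapse = ", "))

  role <- function(ch) ann$role[match(ch, ann$chain_id)]
  mol <- function(ch) ann$mol_id[match(ch, ann$chain_id)]
  htype <- function(ch) ann$histone_type[match(ch, ann$chain_id)]

  ra <- role(contacts$chain_a); rb <- role(contacts$chain_b)
  # orientation priority: histone < partner < dna
  pr <- c(histone = 1L, partner = 2L, dna = 3L)
  swap <- pr[rb] < pr[ra]
  e <- contacts
  for (cols in list(c("chain_a", "chain_b"), c("resid_a", "resid_b"),
                    c("resname_a", "resname_b"))) {
    tmp <- e[[cols[1]]][swap]
    e[[cols[1]]][swap] <- e[[cols[2]]][swap]
    e[[cols[2]]][swap] <- tmp
  }
  ra2 <- role(e$chain_a); rb2 <- role(e$chain_b)
  cls <- mapply(.class_from_roles, ra2, rb2, USE.NAMES = FALSE)

  seq_pos <- function(ch, resid) {
    hit <- match(paste(ch, resid),
                 paste(structure$atoms$chain_id,
                       structure$atoms$residue_seq_id))
    structure$atoms$sequence_position[hit]
  }
  ptm_of <- function(resname) {
    out <- unname(ptm_map[resname])
    out[is.na(match(resname, names(ptm_map)))] <- NA_character_
    out
  }
  ptm_a <- ptm_of(e$resname_a)
  ptm_b <- ptm_of(e$resname_b)
  ptm <- ifelse(!is.na(ptm_a), ptm_a, ptm_b)

  edges <- data.frame(
    structure_id = structure$structure_id,
    class = cls,
    chain_a = e$chain_a, resid_a = e$resid_a, resname_a = e$resname_a,
    seq_pos_a = seq_pos(e$chain_a, e$resid_a),
    chain_b = e$chain_b, resid_b = e$resid_b, resname_b = e$resname_b,
    seq_pos_b = seq_pos(e$chain_b, e$resid_b),
    min_dist = e$min_distance,
    n_atom_contacts = e$atom_contact_count,
    ptm_type = ptm,
    mol_a = mol(e$chain_a), mol_b = mol(e$chain_b),
    role_a = ra2, role_b = rb2,
    histone_type_a = htype(e$chain_a), histone_type_b = htype(e$chain_b),
    organism = organism,
    stringsAsFactors = FALSE
  )

  classes <- c("HHI", "HDI", "HPI", "DPI")
  interface_residues <- lapply(classes, function(k) {
    sub <- edges[edges$class == k, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(chain_id = character(0), residue_seq_id = integer(0),
                        sequence_position = integer(0),
                        residue_name = character(0), role = character(0),
                        histone_type = character(0), ptm_type = character(0),
                        stringsAsFactors = FALSE))
    }
    res <- rbind(
      data.frame(chain_id = sub$chain_a, residue_seq_id = sub$resid_a,
                 sequence_position = sub$seq_pos_a,
                 residue_name = sub$resname_a, role = sub$role_a,
                 histone_type = sub$histone_type_a,
                 stringsAsFactors = FALSE),
      data.frame(chain_id = sub$chain_b, residue_seq_id = sub$resid_b,
                 sequence_position = sub$seq_pos_b,
                 residue_name = sub$resname_b, role = sub$role_b,
                 histone_type = sub$histone_type_b,
                 stringsAsFactors = FALSE))
    res <- res[!duplicated(paste(res$chain_id, res$residue_seq_id)), ]
    res$ptm_type <- ptm_of(res$residue_name)
    rownames(res) <- NULL
    res
  })
  names(interface_residues) <- classes
  list(edges = edges, interface_residues = interface_residues)
}

#' Report contacts at PTM sites
#'
#' Every histone-partner edge whose histone residue is a mapped modified
#' component is reported with its PTM type.
#'
#' @param edges edge table from [extract_interfaces()].
#' @param ptm_map named vector component id -> PTM type.
#' @return data.frame: structure_id, site (mol:position), chain_id, resid,
#'   residue_name, ptm_type, partner.
#' @export
detect_ptm_contacts <- function(edges, ptm_map = default_ptm_map()) {
  sub <- edges[edges$class == "HPI" &
                 edges$resname_a %in% names(ptm_map), , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(structure_id = character(0), site = character(0),
                      chain_id = character(0), resid = integer(0),
                      residue_name = character(0), ptm_type = character(0),
                      partner = character(0), stringsAsFactors = FALSE))
  }
  pos <- ifelse(is.na(sub$seq_pos_a), sub$resid_a, sub$seq_pos_a)
  out <- data.frame(
    structure_id = sub$structure_id,
    site = paste0(sub$mol_a, ":", pos),
    chain_id = sub$chain_a, resid = sub$resid_a,
    residue_name = sub$resname_a,
    ptm_type = unname(ptm_map[sub$resname_a]),
    partner = sub$mol_b,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write an interface edge table to TSV
#' @param edges edge table from [extract_interfaces()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interface_tsv <- function(edges, path) {
  lead <- c("structure_id", "class", "chain_a", "resid_a", "resname_a",
            "seq_pos_a", "chain_b", "resid_b", "resname_b", "seq_pos_b",
            "min_dist", "n_atom_contacts", "ptm_type")
  cols <- c(lead, setdiff(names(edges), lead))
  utils::write.table(edges[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
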