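# Structure parsing, chain typing and coordinate bookkeeping.
#
# A structure is a light S3 container: an atom table (polymer atoms of model
# 1), a chain table, and a ligand table (waters and non-polymer components).
# Parsing is delegated to bio3d (read.pdb / read.cif); entity descriptions and
# resolution are recovered from the header text because downstream chain
# classification and representative selection consume them.

#' Construct a structure object from an atom table
#'
#' Programmatic constructor used by the synthetic generators and available for
#' building structures in code. Heavy-atom flags and per-chain molecule
#' classes are derived, not taken on trust.
#'
#' @param atoms data.frame with columns chain_id, residue_seq_id,
#'   residue_name, atom_name, element, x, y, z (and optionally altloc,
#'   is_hetatm).
#' @param entity_names optional named character vector chain_id -> entity
#'   description (free text).
#' @param structure_id identifier for provenance (defaults to "structure").
#' @param resolution optional resolution in Angstrom.
#' @param ligands optional data.frame of non-polymer atoms (same columns).
#' @return An object of class `histone_structure`.
#' @export
structure_from_atoms <- function(atoms, entity_names = NULL,
                                 structure_id = "structure",
                                 resolution = NA_real_, ligands = NULL) {
  required <- c("chain_id", "residue_seq_id", "residue_name", "atom_name",
                "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_seq_id <- as.integer(atoms$residue_seq_id)
  atoms$element <- as.character(atoms$element)
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) atoms$element[blank] <- .infer_element(atoms$atom_name[blank])
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  atoms$is_heavy <- .is_heavy_element(atoms$element)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$sequence_position)) atoms$sequence_position <- NA_integer_
  atoms <- atoms[order(match(atoms$chain_id, unique(atoms$chain_id)),
                       atoms$residue_seq_id), , drop = FALSE]
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0L) stop("empty structure: no polymer atoms")

  chains <- .build_chain_table(atoms, entity_names)
  if (is.null(ligands)) {
    ligands <- atoms[0, , drop = FALSE]
  }
  structure(list(atoms = atoms, chains = chains, ligands = ligands,
                 structure_id = structure_id,
                 resolution = as.numeric(resolution)),
            class = "histone_structure")
}

.build_chain_table <- function(atoms, entity_names = NULL) {
  ids <- unique(atoms$chain_id)
  cls <- vapply(ids, function(ch) {
    res <- atoms$residue_name[atoms$chain_id == ch]
    res <- res[!duplicated(paste(atoms$residue_seq_id[atoms$chain_id == ch]))]
    n_prot <- sum(.is_protein_component(res))
    n_dna <- sum(.is_dna_component(res))
    n_rna <- sum(.is_rna_component(res))
    counts <- c(protein = n_prot, dna = n_dna, rna = n_rna)
    if (all(counts == 0)) return("other")
    win <- names(counts)[which.max(counts)]
    if (counts[[win]] < length(res)) {
      warning("chain ", ch, " has mixed composition; classed as ", win,
              " by majority", call. = FALSE)
    }
    win
  }, character(1))
  ent <- rep(NA_character_, length(ids))
  if (!is.null(entity_names)) {
    hit <- match(ids, names(entity_names))
    ent[!is.na(hit)] <- unname(entity_names[hit[!is.na(hit)]])
  }
  data.frame(chain_id = ids, molecule_class = unname(cls),
             entity_name = ent, uniprot_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF (first model only). Alternate locations other than
#' blank/'A' are discarded; waters and non-polymer components are moved to a
#' ligand table, while modified polymer residues (e.g. ALY, M3L) stay in the
#' polymer so PTM-site contacts remain detectable.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension).
#' @return A `histone_structure`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("parse error in ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || !nrow(at)) {
    stop("parse error in ", format, " file '", path,
         "': no atom records found")
  }
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]

  element <- at$elesy
  if (is.null(element)) element <- rep("", nrow(at))
  element[is.na(element) | element == ""] <-
    .infer_element(at$elety[is.na(element) | element == ""])

  atoms_all <- data.frame(
    chain_id = as.character(at$chain),
    residue_seq_id = as.integer(at$resno),
    residue_name = toupper(as.character(at$resid)),
    atom_name = as.character(at$elety),
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    record = as.character(at$type),
    stringsAsFactors = FALSE
  )
  is_water <- atoms_all$residue_name %in% .WATER_COMPONENTS
  is_polymer_comp <- .is_protein_component(atoms_all$residue_name) |
    .is_dna_component(atoms_all$residue_name) |
    .is_rna_component(atoms_all$residue_name)
  polymer <- !is_water & (atoms_all$record == "ATOM" | is_polymer_comp)
  ligands <- atoms_all[!polymer, , drop = FALSE]
  atoms <- atoms_all[polymer, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("empty structure: no polymer chains in '", path, "'")
  }

  header <- .read_header_text(path)
  entity_names <- if (format == "pdb") .parse_compnd(header)
                  else .parse_cif_entities(header)
  resolution <- if (format == "pdb") .parse_pdb_resolution(header)
                else .parse_cif_resolution(header)

  st <- structure_from_atoms(atoms[, c("chain_id", "residue_seq_id",
                                       "residue_name", "atom_name", "element",
                                       "x", "y", "z", "altloc")],
                             entity_names = entity_names,
                             structure_id = sub("\\.[^.]*$", "",
                                                basename(path)),
                             resolution = resolution)
  st$ligands <- ligands
  st
}

.read_header_text <- function(path) {
  readLines(path, warn = FALSE)
}

# COMPND blocks: MOL_ID / MOLECULE / CHAIN triples.
.parse_compnd <- function(lines) {
  cmp <- grep("^COMPND", lines, value = TRUE)
  if (!length(cmp)) return(NULL)
  body <- sub("^COMPND\\s{0,4}\\d*\\s*", "", cmp)
  mol <- NA_character_
  out <- character(0)
  for (b in body) {
    b <- trimws(sub(";\\s*$", "", b))
    if (grepl("^MOLECULE:", b)) {
      mol <- trimws(sub("^MOLECULE:\\s*", "", b))
    } else if (grepl("^CHAIN:", b)) {
      chains <- trimws(strsplit(sub("^CHAIN:\\s*", "", b), ",")[[1]])
      if (!is.na(mol)) {
        v <- rep(mol, length(chains)); names(v) <- chains
        out <- c(out, v)
      }
    }
  }
  if (!length(out)) NULL else out
}

.parse_pdb_resolution <- function(lines) {
  r2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(r2)) return(NA_real_)
  m <- regmatches(r2[1], regexpr("[0-9]+\\.[0-9]+", r2[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

# Minimal scan of _entity / _entity_poly blocks for chain descriptions.
.parse_cif_entities <- function(lines) {
  desc <- .cif_loop_table(lines, "_entity.",
                          c("_entity.id", "_entity.pdbx_description"))
  strand <- .cif_loop_table(lines, "_entity_poly.",
                            c("_entity_poly.entity_id",
                              "_entity_poly.pdbx_strand_id"))
  if (is.null(desc) || is.null(strand)) return(NULL)
  out <- character(0)
  for (i in seq_len(nrow(strand))) {
    eid <- strand[i, "_entity_poly.entity_id"]
    d <- desc[desc[, "_entity.id"] == eid, "_entity.pdbx_description"]
    if (!length(d)) next
    chains <- trimws(strsplit(strand[i, "_entity_poly.pdbx_strand_id"],
                              ",")[[1]])
    v <- rep(d[1], length(chains)); names(v) <- chains
    out <- c(out, v)
  }
  if (!length(out)) NULL else out
}

.parse_cif_resolution <- function(lines) {
  hit <- grep("^_refine\\.ls_d_res_high|^_em_3d_reconstruction\\.resolution",
              lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  m <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", hit[1]))
  if (!length(m)) NA_real_ else as.numeric(trimws(m))
}

# Parse one simple mmCIF loop into a character matrix (quoted tokens allowed).
.cif_loop_table <- function(lines, prefix, wanted) {
  starts <- which(trimws(lines) == "loop_")
  for (s in starts) {
    i <- s + 1
    cols <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), prefix)) {
      cols <- c(cols, trimws(lines[i])); i <- i + 1
    }
    if (!all(wanted %in% cols)) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || ln %in% c("loop_", "#") ||
          startsWith(ln, "data_")) break
      toks <- .cif_tokens(ln)
      if (length(toks) == length(cols)) rows[[length(rows) + 1]] <- toks
      i <- i + 1
    }
    if (!length(rows)) return(NULL)
    mat <- do.call(rbind, rows)
    colnames(mat) <- cols
    return(mat[, wanted, drop = FALSE])
  }
  NULL
}

.cif_tokens <- function(line) {
  toks <- regmatches(line,
                     gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Write a structure to a PDB-format file
#'
#' Emits COMPND entity blocks, a REMARK 2 resolution record when known, and
#' fixed-width ATOM/HETATM records. Modified polymer residues are written as
#' HETATM; output is byte-deterministic for a given structure.
#'
#' @param structure a `histone_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "histone_structure"))
  at <- structure$atoms
  lines <- character(0)
  ch <- structure$chains
  have_names <- !is.na(ch$entity_name)
  if (any(have_names)) {
    mol_id <- 0
    for (nm in unique(ch$entity_name[have_names])) {
      mol_id <- mol_id + 1
      ids <- ch$chain_id[have_names & ch$entity_name == nm]
      lines <- c(lines,
                 sprintf("COMPND %3d MOL_ID: %d;", mol_id, mol_id),
                 sprintf("COMPND %3d MOLECULE: %s;", mol_id, nm),
                 sprintf("COMPND %3d CHAIN: %s;", mol_id,
                         paste(ids, collapse = ", ")))
    }
  }
  if (!is.na(structure$resolution)) {
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", structure$resolution))
  }
  serial <- 0L
  for (chain in unique(at$chain_id)) {
    rows <- which(at$chain_id == chain)
    for (i in rows) {
      serial <- serial + 1L
      rec <- if (at$residue_name[i] %in% .AA3 ||
                 .is_dna_component(at$residue_name[i]) ||
                 .is_rna_component(at$residue_name[i])) "ATOM" else "HETATM"
      nm <- at$atom_name[i]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial %% 100000L, nm_fmt, at$residue_name[i], chain,
        at$residue_seq_id[i], at$x[i], at$y[i], at$z[i], 1, 0,
        at$element[i]))
    }
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              (serial + 1L) %% 100000L,
                              at$residue_name[rows[length(rows)]], chain,
                              at$residue_seq_id[rows[length(rows)]]))
    serial <- serial + 1L
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.histone_structure <- function(x, ...) {
  cat("histone_structure '", x$structure_id, "': ",
      nrow(x$chains), " chains, ", nrow(x$atoms), " polymer atoms",
      if (!is.na(x$resolution)) sprintf(", %.2f A", x$resolution) else "",
      "\n", sep = "")
  invisible(x)
}

# ---- chain classification ---------------------------------------------------

#' Default histone recognition configuration
#'
#' Keywords and reference sequences per histone type, loaded from the bundled
#' YAML config. Users can supply their own file via [load_histone_config()];
#' the bundled keyword list is an editable approximation of the keyword sets
#' commonly used to retrieve histone entries.
#'
#' @return list with elements `types` (named list of keywords / reference) and
#'   `identity_threshold`.
#' @export
default_histone_config <- function() {
  load_histone_config(system.file("extdata", "histone_config.yaml",
                                  package = "histonet"))
}

#' Load a histone recognition configuration from YAML
#' @param path YAML file with per-type keywords and optional reference
#'   sequences.
#' @return configuration list (see [default_histone_config()]).
#' @export
load_histone_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$types) || !length(cfg$types)) {
    stop("configuration error: no histone types defined in ", path)
  }
  if (is.null(cfg$identity_threshold)) cfg$identity_threshold <- 0.6
  cfg
}

.slug <- function(x) {
  s <- tolower(gsub("[^A-Za-z0-9.]+", "_", trimws(x)))
  gsub("^_+|_+$", "", s)
}

.chain_sequence <- function(structure, chain) {
  at <- structure$atoms[structure$atoms$chain_id == chain, ]
  res <- at[!duplicated(at$residue_seq_id), "residue_name"]
  one <- .AA1[res]
  # modified residues fall back to their parent amino acid where obvious
  parent <- c(ALY = "K", MLZ = "K", MLY = "K", M3L = "K", KCR = "K",
              SEP = "S", TPO = "T", PTR = "Y", CIR = "R", AGM = "R",
              DA2 = "R")
  one[is.na(one)] <- parent[res[is.na(one)]]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

.seq_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) return(0)
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       substitutionMatrix = NULL,
                                       type = "global",
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  # global identity: matches over the longer sequence length, so fragments
  # cannot score as full-length matches
  sum(pa == ps & pa != "-") / max(nchar(a), nchar(b))
}

#' Classify chains into histone / partner / DNA roles
#'
#' Protein chains whose entity name matches a configured histone keyword, or
#' whose sequence identity to a reference histone sequence meets the
#' configured threshold, are annotated as histones with their type; all other
#' protein chains become partners and nucleic chains become DNA.
#'
#' @param structure a `histone_structure`.
#' @param histone_config configuration list (see [default_histone_config()]).
#' @return data.frame with chain_id, role, histone_type, variant_label and
#'   mol_id (molecule identity used for network nodes).
#' @export
classify_chains <- function(structure, histone_config = default_histone_config()) {
  stopifnot(inherits(structure, "histone_structure"))
  if (is.null(histone_config$types) || !length(histone_config$types)) {
    stop("configuration error: empty histone configuration")
  }
  ch <- structure$chains
  out <- data.frame(chain_id = ch$chain_id, role = NA_character_,
                    histone_type = NA_character_,
                    variant_label = NA_character_,
                    mol_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ch))) {
    cls <- ch$molecule_class[i]
    if (cls %in% c("dna", "rna")) {
      out$role[i] <- if (cls == "dna") "dna" else "partner"
      out$mol_id[i] <- if (cls == "dna") "DNA" else
        .partner_id(ch$uniprot_id[i], ch$entity_name[i], ch$chain_id[i])
      next
    }
    nm <- ch$entity_name[i]
    type <- NA_character_
    if (!is.na(nm)) {
      low <- tolower(nm)
      for (ht in names(histone_config$types)) {
        kw <- histone_config$types[[ht]]$keywords
        if (length(kw) && any(vapply(kw, function(k)
          grepl(tolower(k), low, fixed = TRUE), logical(1)))) {
          type <- ht; break
        }
      }
    }
    if (is.na(type)) {
      refs <- vapply(histone_config$types,
                     function(t) t$reference %||% "", character(1))
      refs <- refs[nchar(refs) > 0]
      if (length(refs)) {
        seq <- .chain_sequence(structure, ch$chain_id[i])
        ids <- vapply(refs, function(r) .seq_identity(seq, r), numeric(1))
        if (max(ids) >= histone_config$identity_threshold) {
          type <- names(refs)[which.max(ids)]
        }
      }
    }
    if (!is.na(type)) {
      out$role[i] <- "histone"
      out$histone_type[i] <- type
      out$variant_label[i] <- if (!is.na(nm)) nm else paste("Histone", type)
      out$mol_id[i] <- .slug(out$variant_label[i])
    } else {
      out$role[i] <- "partner"
      out$mol_id[i] <- .partner_id(ch$uniprot_id[i], nm, ch$chain_id[i])
    }
  }
  out
}

.partner_id <- function(uniprot, entity, chain) {
  if (!is.na(uniprot) && nzchar(uniprot)) return(uniprot)
  if (!is.na(entity) && nzchar(entity)) return(.slug(entity))
  paste0("chain_", chain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- residue mapping --------------------------------------------------------

#' Read a residue-number mapping table
#'
#' TSV with header `chain_id, struct_resid, seq_pos, uniprot_id`, mapping
#' structure numbering to 1-based sequence coordinates (SIFTS-like).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_residue_mapping <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chain_id", "struct_resid", "seq_pos")
  miss <- setdiff(required, names(m))
  if (length(miss)) stop("mapping table lacks column(s): ",
                         paste(miss, collapse = ", "))
  m
}

#' Apply a sequence-coordinate mapping to a structure
#'
#' Attaches `sequence_position` to every mapped residue. `"identity"` sets
#' the sequence position equal to the structure residue number; unmapped
#' residues carry NA and are excluded from sequence-coordinate outputs.
#'
#' @param structure a `histone_structure`.
#' @param mapping `"identity"` or a data.frame from [read_residue_mapping()].
#' @return the structure with sequence positions attached.
#' @export
apply_residue_mapping <- function(structure, mapping = "identity") {
  stopifnot(inherits(structure, "histone_structure"))
  at <- structure$atoms
  if (identical(mapping, "identity")) {
    at$sequence_position <- at$residue_seq_id
    structure$atoms <- at
    return(structure)
  }
  key <- paste(mapping$chain_id, mapping$struct_resid)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("mapping conflict: duplicate rows for (chain, residue) ",
         paste(dup, collapse = "; "))
  }
  unknown <- setdiff(unique(mapping$chain_id), structure$chains$chain_id)
  if (length(unknown)) {
    stop("mapping references unknown chain(s): ",
         paste(unknown, collapse = ", "))
  }
  hit <- match(paste(at$chain_id, at$residue_seq_id), key)
  at$sequence_position <- ifelse(is.na(hit), NA_integer_,
                                 as.integer(mapping$seq_pos[hit]))
  structure$atoms <- at
  if ("uniprot_id" %in% names(mapping)) {
    up <- unique(mapping[!is.na(mapping$uniprot_id),
                         c("chain_id", "uniprot_id")])
    hit <- match(structure$chains$chain_id, up$chain_id)
    structure$chains$uniprot_id[!is.na(hit)] <- up$uniprot_id[hit[!is.na(hit)]]
  }
  structure
}

#' Subset a structure to a set of chains
#'
#' Used before binding free energy calculations on histone-histone and
#' histone-DNA interfaces, where partner chains are removed from the complex.
#' The input structure is left unmodified.
#'
#' @param structure a `histone_structure`.
#' @param keep character vector of chain ids to retain.
#' @return a new `histone_structure` with exactly the kept chains.
#' @export
prune_chains <- function(structure, keep) {
  stopifnot(inherits(structure, "histone_structure"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, structure$chains$chain_id)
  if (length(unknown)) {
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  }
  if (!length(keep)) stop("empty structure: no chains kept")
  out <- structure
  out$atoms <- structure$atoms[structure$atoms$chain_id %in% keep, ,
                               drop = FALSE]
  rownames(out$atoms) <- NULL
  out$chains <- structure$chains[structure$chains$chain_id %in% keep, ,
                                 drop = FALSE]
  rownames(out$chains) <- NULL
  if (nrow(out$ligands)) {
    out$ligands <- structure$ligands[structure$ligands$chain_id %in% keep, ,
                                     drop = FALSE]
  }
  out
}
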