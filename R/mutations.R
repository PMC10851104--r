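# Curation of cancer-associated histone mutations, interface mapping,
# physicochemical profiling, pluggable binding free energy change (ddG)
# prediction and disruptive-mutation calling.
#
# Filters follow the curation protocol: targeted-sequencing records and
# somatic-unmatched samples are excluded from the combined set; the refined
# set further drops samples with tumor mutation burden > 10 mutations/Mb
# (strict), dbSNP-known variants, and keeps mutations recurring in at least
# three distinct samples.

#' Parse a mutation table
#'
#' TSV with headers gene, protein_change, sample_id, cancer_type,
#' variant_class, sequencing_type, somatic_status and optional sample_tmb,
#' in_dbsnp. Protein-change strings of the form "R29P" are decomposed;
#' malformed rows are collected in a reject report rather than silently
#' dropped.
#'
#' @param path TSV path.
#' @return list with `records` (parsed data.frame with wt_aa, position,
#'   mut_aa) and `rejects` (malformed rows with a reason column).
#' @export
parse_mutations <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene", "protein_change", "sample_id", "cancer_type",
                "variant_class", "sequencing_type", "somatic_status")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop("mutation table lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(raw$sample_tmb)) raw$sample_tmb <- NA
  if (is.null(raw$in_dbsnp)) raw$in_dbsnp <- "FALSE"
  m <- regexec("^([A-Z])([0-9]+)([A-Z*])$", raw$protein_change)
  parts <- regmatches(raw$protein_change, m)
  ok <- lengths(parts) == 4
  rejects <- raw[!ok, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- "unparseable protein change"
  rec <- raw[ok, , drop = FALSE]
  pm <- do.call(rbind, parts[ok])
  rec$wt_aa <- pm[, 2]
  rec$position <- as.integer(pm[, 3])
  rec$mut_aa <- pm[, 4]
  rec$sample_tmb <- suppressWarnings(as.numeric(rec$sample_tmb))
  rec$in_dbsnp <- toupper(rec$in_dbsnp) %in% c("TRUE", "1", "YES")
  bad_pos <- rec$position < 1
  same <- rec$variant_class == "missense" & rec$wt_aa == rec$mut_aa
  drop <- bad_pos | same
  if (any(drop)) {
    extra <- rec[drop, setdiff(names(rec), c("wt_aa", "position", "mut_aa")),
                 drop = FALSE]
    extra$reason <- ifelse(bad_pos[drop], "position < 1",
                           "wild-type equals mutant")
    rejects <- rbind(rejects, extra)
  }
  rec <- rec[!drop, , drop = FALSE]
  rownames(rec) <- NULL
  rownames(rejects) <- NULL
  list(records = rec, rejects = rejects)
}

.mutation_key <- function(records) {
  paste0(records$gene, ":", records$wt_aa, records$position, records$mut_aa)
}

.recurrence_table <- function(records) {
  if (!nrow(records)) {
    return(data.frame(mutation = character(0), n_samples = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- .mutation_key(records)
  rec <- tapply(records$sample_id, key, function(v) length(unique(v)))
  data.frame(mutation = names(rec), n_samples = as.integer(rec),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the combined mutation set
#'
#' Drops targeted-sequencing records and somatic-unmatched samples, keeps
#' missense calls, unions with an optional external set and deduplicates on
#' (gene, protein change, sample).
#'
#' @param records parsed records from [parse_mutations()].
#' @param external_set optional second record table with the same columns.
#' @return list of class `mutation_set`: label, records, recurrence.
#' @export
build_combined_set <- function(records, external_set = NULL) {
  filt <- function(r) {
    r <- r[r$sequencing_type != "targeted", , drop = FALSE]
    r <- r[r$somatic_status != "unmatched", , drop = FALSE]
    r[r$variant_class == "missense", , drop = FALSE]
  }
  rec <- filt(records)
  if (!is.null(external_set) && nrow(external_set)) {
    common <- intersect(names(rec), names(external_set))
    rec <- rbind(rec[, common, drop = FALSE],
                 filt(external_set)[, common, drop = FALSE])
  }
  dedup_key <- paste(rec$gene, rec$wt_aa, rec$position, rec$mut_aa,
                     rec$sample_id)
  rec <- rec[!duplicated(dedup_key), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(label = "combined", records = rec,
                 recurrence = .recurrence_table(rec)),
            class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat("mutation_set '", x$label, "': ", nrow(x$records), " records, ",
      nrow(x$recurrence), " distinct mutations\n", sep = "")
  invisible(x)
}

#' Build the refined mutation set
#'
#' From the combined set: drops records from samples with tumor mutation
#' burden strictly above `tmb_cutoff` mutations/Mb, drops dbSNP-known
#' variants, then keeps mutations recurring in at least `recurrence_min`
#' distinct samples (recurrence computed after the preceding filters, keyed
#' on gene + amino-acid change, across cancer types).
#'
#' @param combined a `mutation_set` from [build_combined_set()].
#' @param tmb_cutoff TMB threshold, mutations/Mb (strict `>` drops).
#' @param recurrence_min minimum distinct-sample recurrence (`>=` keeps).
#' @param callable_mb callable territory used to derive TMB for samples
#'   lacking the column (per-sample record count / callable_mb).
#' @param derive_tmb derive missing TMB values; if FALSE, samples with
#'   missing TMB raise an error listing their ids.
#' @return a `mutation_set` labeled "refined".
#' @export
build_refined_set <- function(combined, tmb_cutoff = 10.0,
                              recurrence_min = 3, callable_mb = 38,
                              derive_tmb = TRUE) {
  rec <- combined$records
  if (!nrow(rec)) {
    return(structure(list(label = "refined", records = rec,
                          recurrence = .recurrence_table(rec)),
                     class = "mutation_set"))
  }
  tmb <- rec$sample_tmb
  if (anyNA(tmb)) {
    if (!derive_tmb) {
      stop("tumor mutation burden underivable for sample(s): ",
           paste(unique(rec$sample_id[is.na(tmb)]), collapse = ", "))
    }
    counts <- table(rec$sample_id)
    derived <- as.numeric(counts[rec$sample_id]) / callable_mb
    tmb[is.na(tmb)] <- derived[is.na(tmb)]
  }
  rec <- rec[tmb <= tmb_cutoff, , drop = FALSE]
  rec <- rec[!rec$in_dbsnp, , drop = FALSE]
  recur <- .recurrence_table(rec)
  keep_keys <- recur$mutation[recur$n_samples >= recurrence_min]
  rec <- rec[.mutation_key(rec) %in% keep_keys, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(label = "refined", records = rec,
                 recurrence = .recurrence_table(rec)),
            class = "mutation_set")
}

#' Map mutations onto residue-level binding interfaces
#'
#' A mutation maps to an interaction class when its (gene product, position)
#' residue node participates in at least one edge of that class in the
#' residue-level network; one mutation may map to several classes, and
#' mutations on all three histone interface types (HHI, HDI, HPI) are
#' reported separately.
#'
#' @param mset a `mutation_set`.
#' @param net a residue-level `hinet`.
#' @param gene_map optional data.frame (gene, protein) translating gene
#'   symbols to the network's molecule ids; defaults to identity.
#' @return list: `per_class` (named list of mutation keys per HHI/HDI/HPI),
#'   `multi` (keys on all three), `unmapped` (keys with no interface node),
#'   and `mapping` (long data.frame mutation x class).
#' @export
map_mutations_to_interfaces <- function(mset, net, gene_map = NULL) {
  rec <- mset$records
  classes <- c("HDI", "HHI", "HPI")
  if (!nrow(rec)) {
    empty <- stats::setNames(vector("list", 3), classes)
    empty <- lapply(empty, function(x) character(0))
    return(list(per_class = empty, multi = character(0),
                unmapped = character(0),
                mapping = data.frame(mutation = character(0),
                                     class = character(0))))
  }
  uniq <- rec[!duplicated(.mutation_key(rec)), , drop = FALSE]
  keys <- .mutation_key(uniq)
  prot <- uniq$gene
  if (!is.null(gene_map)) {
    hit <- match(uniq$gene, gene_map$gene)
    prot[!is.na(hit)] <- gene_map$protein[hit[!is.na(hit)]]
  }
  node_ids <- paste0(prot, ":", uniq$position)
  ed <- net$edges
  node_classes <- function(id) {
    unique(ed$interaction_class[ed$node_a == id | ed$node_b == id])
  }
  per <- stats::setNames(lapply(classes, function(k) character(0)), classes)
  multi <- character(0)
  unmapped <- character(0)
  map_rows <- list()
  for (i in seq_along(keys)) {
    cls <- intersect(node_classes(node_ids[i]), classes)
    if (!length(cls)) {
      unmapped <- c(unmapped, keys[i])
      next
    }
    for (k in cls) per[[k]] <- c(per[[k]], keys[i])
    if (all(classes %in% cls)) multi <- c(multi, keys[i])
    map_rows[[length(map_rows) + 1]] <-
      data.frame(mutation = keys[i], class = cls, stringsAsFactors = FALSE)
  }
  list(per_class = per, multi = multi, unmapped = unmapped,
       mapping = if (length(map_rows)) do.call(rbind, map_rows)
                 else data.frame(mutation = character(0),
                                 class = character(0)))
}

#' Physicochemical category of an amino acid
#'
#' Fixed five-way partition of the 20 standard residues: positive {K, R, H},
#' negative {D, E}, polar uncharged {S, T, N, Q, C}, nonpolar aliphatic
#' {G, A, V, L, I, M, P}, nonpolar aromatic {F, W, Y}.
#'
#' @param aa character vector of 1-letter amino acid codes.
#' @return character vector of categories.
#' @export
classify_physchem <- function(aa) {
  map <- c(K = "positive", R = "positive", H = "positive",
           D = "negative", E = "negative",
           S = "polar_uncharged", T = "polar_uncharged",
           N = "polar_uncharged", Q = "polar_uncharged",
           C = "polar_uncharged",
           G = "nonpolar_aliphatic", A = "nonpolar_aliphatic",
           V = "nonpolar_aliphatic", L = "nonpolar_aliphatic",
           I = "nonpolar_aliphatic", M = "nonpolar_aliphatic",
           P = "nonpolar_aliphatic",
           F = "nonpolar_aromatic", W = "nonpolar_aromatic",
           Y = "nonpolar_aromatic")
  aa <- toupper(aa)
  bad <- !aa %in% names(map)
  if (any(bad)) {
    stop("nonstandard amino acid letter(s): ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  unname(map[aa])
}

#' Wild-type versus mutant physicochemical profiles
#'
#' @param records mutation records (wt_aa / mut_aa columns), typically the
#'   interface-mapped subset.
#' @return data.frame: category, wt_count, mut_count.
#' @export
profile_interface_change <- function(records) {
  cats <- c("polar_uncharged", "nonpolar_aliphatic", "nonpolar_aromatic",
            "negative", "positive")
  wt <- table(factor(classify_physchem(records$wt_aa), levels = cats))
  mt <- table(factor(classify_physchem(records$mut_aa), levels = cats))
  data.frame(category = cats, wt_count = as.integer(wt),
             mut_count = as.integer(mt), stringsAsFactors = FALSE)
}

# ---- ddG prediction ---------------------------------------------------------

#' Deterministic surrogate ddG predictor
#'
#' A labeled NON-PHYSICAL stand-in satisfying the predictor plugin contract
#' `(structure, chain, position, wt, mut, mode) -> kcal/mol` for testing and
#' continuous integration. The score is a fixed function of the charge,
#' hydropathy and volume differences of the substitution (structure
#' independent, positive = destabilizing); it carries no trained energetics
#' and must not be used for scientific inference.
#'
#' @return a predictor function with attribute `predictor_id`.
#' @export
ddg_surrogate_predictor <- function() {
  charge <- c(K = 1, R = 1, H = 0.5, D = -1, E = -1)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  vol <- c(A = 89, R = 174, N = 114, D = 111, C = 109, Q = 144, E = 138,
           G = 60, H = 153, I = 167, L = 167, K = 169, M = 163, F = 190,
           P = 113, S = 89, T = 116, W = 228, Y = 194, V = 140)
  f <- function(structure, chain, position, wt, mut, mode) {
    q <- abs((charge[wt] %||na% 0) - (charge[mut] %||na% 0))
    h <- abs(kd[[wt]] - kd[[mut]])
    v <- abs(vol[[wt]] - vol[[mut]])
    w_q <- if (identical(mode, "protein-dna")) 1.3 else 0.9
    unname(w_q * q + 0.12 * h + 0.004 * v)
  }
  attr(f, "predictor_id") <- "surrogate-physchem-v1"
  f
}

`%||na%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || is.na(a)) b else a
}

#' Predict the binding free energy change of one mutation
#'
#' Dispatches to a registered predictor under the plugin contract
#' `(structure, chain, position, wt, mut, mode) -> kcal/mol` (positive =
#' destabilizing). For HHI and HDI requests the partner chains are removed
#' from the complex before prediction; for HPI the partner-containing
#' complex is used. Mutations whose position is absent from the structure
#' are skipped with a reason; predictor failures are recorded, not fatal.
#'
#' @param mutation list or one-row data.frame with gene (molecule id),
#'   position, wt_aa, mut_aa.
#' @param structure a `histone_structure` with sequence positions applied.
#' @param annotations chain annotations from [classify_chains()].
#' @param interaction_class "HHI", "HDI" or "HPI".
#' @param predictor predictor function (default the labeled surrogate).
#' @param gene_map optional data.frame (gene, protein) as in
#'   [map_mutations_to_interfaces()].
#' @return one-row data.frame (mutation, interaction_class, ddg,
#'   predictor_id, structure_id, status, reason); ddg is NA when skipped.
#' @export
predict_ddg <- function(mutation, structure, annotations,
                        interaction_class = c("HHI", "HDI", "HPI"),
                        predictor = ddg_surrogate_predictor(),
                        gene_map = NULL) {
  interaction_class <- match.arg(interaction_class)
  mut <- as.list(mutation)
  prot <- mut$gene
  if (!is.null(gene_map)) {
    hit <- match(mut$gene, gene_map$gene)
    if (!is.na(hit)) prot <- gene_map$protein[hit]
  }
  key <- paste0(mut$gene, ":", mut$wt_aa, mut$position, mut$mut_aa)
  pid <- attr(predictor, "predictor_id") %||% "custom"
  row <- function(ddg, status, reason = NA_character_) {
    data.frame(mutation = key, interaction_class = interaction_class,
               ddg = ddg, predictor_id = pid,
               structure_id = structure$structure_id,
               status = status, reason = reason, stringsAsFactors = FALSE)
  }
  cand <- annotations$chain_id[annotations$mol_id == prot]
  at <- structure$atoms
  chain <- NA_character_
  for (ch in cand) {
    if (any(at$chain_id == ch &
              !is.na(at$sequence_position) &
              at$sequence_position == mut$position)) { chain <- ch; break }
  }
  if (is.na(chain)) {
    return(row(NA_real_, "skipped", "position absent from structure"))
  }
  st <- structure
  if (interaction_class %in% c("HHI", "HDI")) {
    keep <- annotations$chain_id[annotations$role != "partner"]
    st <- prune_chains(structure, intersect(keep,
                                            structure$chains$chain_id))
  }
  mode <- if (interaction_class == "HDI") "protein-dna" else "protein-protein"
  val <- tryCatch(predictor(st, chain, mut$position, mut$wt_aa, mut$mut_aa,
                            mode),
                  error = function(e) e)
  if (inherits(val, "error")) {
    return(row(NA_real_, "predictor_error", conditionMessage(val)))
  }
  row(as.numeric(val), "ok")
}

#' Select disruptive mutations from ddG records
#'
#' Per-mutation, per-class mean ddG (deduplicated per structure) is compared
#' against class thresholds: histone-DNA >= 1.0 kcal/mol, histone-histone
#' and histone-partner >= 1.5 kcal/mol; only mutations recurring in at least
#' `recurrence_min` samples are eligible.
#'
#' @param ddg_records data.frame with mutation, interaction_class, ddg,
#'   structure_id (rows with NA ddg are ignored).
#' @param recurrence data.frame (mutation, n_samples) as held by a
#'   `mutation_set`.
#' @param thresholds named vector of per-class mean-ddG thresholds.
#' @param recurrence_min recurrence gate (distinct samples).
#' @return data.frame: mutation, interaction_class, mean_ddg, n_structures,
#'   recurrence.
#' @export
select_disruptive <- function(ddg_records, recurrence,
                              thresholds = c(HDI = 1.0, HHI = 1.5,
                                             HPI = 1.5),
                              recurrence_min = 3) {
  dd <- ddg_records[!is.na(ddg_records$ddg), , drop = FALSE]
  if (!nrow(dd)) {
    return(data.frame(mutation = character(0),
                      interaction_class = character(0),
                      mean_ddg = numeric(0), n_structures = integer(0),
                      recurrence = integer(0)))
  }
  # one value per (mutation, class, structure)
  dd <- dd[!duplicated(paste(dd$mutation, dd$interaction_class,
                             dd$structure_id)), , drop = FALSE]
  agg <- stats::aggregate(ddg ~ mutation + interaction_class, data = dd,
                          FUN = mean)
  nst <- stats::aggregate(structure_id ~ mutation + interaction_class,
                          data = dd, FUN = function(v) length(unique(v)))
  agg$n_structures <- nst$structure_id[
    match(paste(agg$mutation, agg$interaction_class),
          paste(nst$mutation, nst$interaction_class))]
  agg$recurrence <- recurrence$n_samples[
    match(agg$mutation, recurrence$mutation)]
  agg$recurrence[is.na(agg$recurrence)] <- 0L
  thr <- thresholds[agg$interaction_class]
  keep <- !is.na(thr) & agg$ddg >= thr & agg$recurrence >= recurrence_min
  out <- agg[keep, , drop = FALSE]
  names(out)[names(out) == "ddg"] <- "mean_ddg"
  out <- out[order(out$interaction_class, out$mutation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare ddG distributions between groups (Tukey HSD)
#'
#' One-way analysis of variance followed by Tukey honestly-significant-
#' difference tests over all group pairs, with significance flags at 0.05
#' and 0.005.
#'
#' @param values numeric ddG values.
#' @param groups grouping factor (histone type or interaction class).
#' @return data.frame: group_a, group_b, diff, p_adj, sig_05, sig_005; group
#'   medians attached as the `medians` attribute.
#' @export
compare_ddg_groups <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("degenerate group(s) with fewer than two values: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  out <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                    diff = tk[, "diff"], p_adj = tk[, "p adj"],
                    stringsAsFactors = FALSE)
  out$sig_05 <- out$p_adj < 0.05
  out$sig_005 <- out$p_adj < 0.005
  rownames(out) <- NULL
  attr(out, "medians") <- tapply(values, groups, stats::median)
  out
}
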