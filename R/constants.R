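# Chemical component vocabularies used across the package.

# Standard amino-acid components plus common modified residues that must stay
# in the polymer (so contacts at PTM sites remain detectable).
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

.DNA_COMPONENTS <- c("DA", "DC", "DG", "DT", "DI", "DU", "5CM", "6MA")
.RNA_COMPONENTS <- c("A", "C", "G", "U", "I", "PSU")
.WATER_COMPONENTS <- c("HOH", "DOD", "WAT", "H2O")

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

#' Default map from modified chemical components to PTM types
#'
#' Chemical component identifiers of post-translationally modified residues
#' mapped to a PTM type label. The map is a plain named character vector and
#' can be extended or replaced by the user; the set shipped here covers the
#' modifications most frequently resolved in histone complex structures
#' (lysine acetylation/methylation/crotonylation and the common
#' phospho-residues).
#'
#' @return Named character vector: component id -> PTM type label.
#' @export
#' @examples
#' default_ptm_map()[["ALY"]]
default_ptm_map <- function() {
  c(ALY = "lysine-acetylation",
    MLZ = "lysine-monomethylation",
    MLY = "lysine-dimethylation",
    M3L = "lysine-trimethylation",
    KCR = "lysine-crotonylation",
    SEP = "serine-phosphorylation",
    TPO = "threonine-phosphorylation",
    PTR = "tyrosine-phosphorylation",
    DA2 = "arginine-dimethylation",
    AGM = "arginine-monomethylation",
    CIR = "citrullination")
}

.MODIFIED_AA <- function(ptm_map = default_ptm_map()) {
  setdiff(names(ptm_map), c("5CM", "6MA"))
}

.is_protein_component <- function(resname, ptm_map = default_ptm_map()) {
  resname %in% .AA3 | resname %in% .MODIFIED_AA(ptm_map)
}

.is_dna_component <- function(resname) resname %in% .DNA_COMPONENTS
.is_rna_component <- function(resname) resname %in% .RNA_COMPONENTS

# Element inference from PDB atom names when the element column is absent:
# the first non-digit character of the (left-stripped) atom name, with the
# common two-letter cases handled explicitly.
.infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Z]", "", atom_name))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")]
  el[nm == ""] <- "X"
  el
}

.is_heavy_element <- function(element) {
  !(toupper(element) %in% c("H", "D", "T"))
}
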