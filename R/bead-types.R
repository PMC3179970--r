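#' @keywords internal
"_PACKAGE"

## United-atom (bead) definitions for the coarse-grained representation.
##
## Protein residues carry one to three beads: the alpha carbon (CA) always,
## a proximal side-chain centroid (SC1) out to the gamma layer, and for the
## larger residues a distal side-chain centroid (SC2).  Every (residue, role)
## combination is a distinct interaction type, so an alanine CA and a lysine
## CA are different types.  Nucleotides carry a phosphate-group centroid (P),
## a ribose centroid (RIB), and one (pyrimidine: PYR) or two (purine: PUR5,
## PUR6) base-ring centroids.

# Side-chain atom membership per bead.  SC1 holds side-chain heavy atoms up
# to the gamma layer; SC2 the remaining distal atoms (3-bead residues only).
.protein_bead_atoms <- list(
  GLY = list(),
  ALA = list(SC1 = "CB"),
  SER = list(SC1 = c("CB", "OG")),
  CYS = list(SC1 = c("CB", "SG")),
  THR = list(SC1 = c("CB", "OG1", "CG2")),
  VAL = list(SC1 = c("CB", "CG1", "CG2")),
  PRO = list(SC1 = c("CB", "CG", "CD")),
  LEU = list(SC1 = c("CB", "CG"), SC2 = c("CD1", "CD2")),
  ILE = list(SC1 = c("CB", "CG1", "CG2"), SC2 = "CD1"),
  MET = list(SC1 = c("CB", "CG"), SC2 = c("SD", "CE")),
  PHE = list(SC1 = c("CB", "CG"), SC2 = c("CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(SC1 = c("CB", "CG"),
             SC2 = c("CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  TYR = list(SC1 = c("CB", "CG"),
             SC2 = c("CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
  ASP = list(SC1 = c("CB", "CG"), SC2 = c("OD1", "OD2")),
  GLU = list(SC1 = c("CB", "CG"), SC2 = c("CD", "OE1", "OE2")),
  ASN = list(SC1 = c("CB", "CG"), SC2 = c("OD1", "ND2")),
  GLN = list(SC1 = c("CB", "CG"), SC2 = c("CD", "OE1", "NE2")),
  LYS = list(SC1 = c("CB", "CG"), SC2 = c("CD", "CE", "NZ")),
  ARG = list(SC1 = c("CB", "CG"), SC2 = c("CD", "NE", "CZ", "NH1", "NH2")),
  HIS = list(SC1 = c("CB", "CG"), SC2 = c("ND1", "CD2", "CE1", "NE2"))
)

.amino3 <- names(.protein_bead_atoms)

.rna_ring6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
.rna_ring5 <- c("C4", "C5", "N7", "C8", "N9")
.rna_ribose <- c("C1'", "C2'", "C3'", "C4'", "O4'")
.rna_phosphate <- c("P", "OP1", "OP2")
.purines <- c("A", "G")
.pyrimidines <- c("C", "U")

# Built-in lookup of posttranscriptionally modified nucleotide codes to
# their canonical parent base.  Unknown codes fall back to a ring-atom
# census (N9 present -> purine).
.modified_nt_lookup <- c(
  PSU = "U", "5MC" = "C", "1MA" = "A", "7MG" = "G", "2MG" = "G",
  M2G = "G", OMC = "C", OMG = "G", H2U = "U", "5MU" = "U", "4SU" = "U",
  I = "G", "1MG" = "G", "6MA" = "A", "4OC" = "C", "5BU" = "U",
  OMU = "U", UR3 = "U", "2MA" = "A", MIA = "A", "66D" = "A", T6A = "A"
)

# Long-form nucleotide names occasionally seen in older files.
.canonical_nt <- c(A = "A", U = "U", G = "G", C = "C",
                   ADE = "A", URA = "U", URI = "U", GUA = "G", CYT = "C",
                   RA = "A", RU = "U", RG = "G", RC = "C")

#' Enumerate the united-atom bead types
#'
#' The coarse-grained alphabet is fixed: 52 protein types (per-residue CA,
#' SC1 and, for the 13 largest residues, SC2 beads) and 14 RNA types
#' (P and RIB for every base, PUR5+PUR6 for purines, PYR for pyrimidines).
#' Type labels are `"<residue>.<role>"`, e.g. `"LYS.SC2"` or `"G.PUR6"`.
#'
#' @return A list with character vectors `protein` and `rna`.
#' @examples
#' length(rnp_bead_types()$protein)  # 52
#' @export
rnp_bead_types <- function() {
  prot <- unlist(lapply(.amino3, function(res) {
    paste(res, c("CA", names(.protein_bead_atoms[[res]])), sep = ".")
  }), use.names = FALSE)
  rna <- unlist(lapply(c("A", "C", "G", "U"), function(res) {
    roles <- if (res %in% .purines) c("P", "RIB", "PUR5", "PUR6")
             else c("P", "RIB", "PYR")
    paste(res, roles, sep = ".")
  }), use.names = FALSE)
  list(protein = prot, rna = rna)
}

#' Map a modified nucleotide code to its canonical parent base
#'
#' Known modified-residue codes (pseudouridine PSU, 5-methylcytosine 5MC,
#' inosine I, ...) are looked up directly; unknown codes are resolved by a
#' ring-atom census: a residue exposing N9 is treated as a purine (parent A
#' by default), any other ring-bearing residue as a pyrimidine (parent U),
#' with a warning in both fallback cases.
#'
#' @param raw_code Residue code as read from the file.
#' @param atom_names Character vector of the residue's atom names.
#' @param modres Optional parent code taken from a MODRES record; overrides
#'   the census-based inference for unknown codes.
#' @return A list with `code` (one of `"A","U","G","C"`) and `is_modified`.
#' @export
map_modified_residue <- function(raw_code, atom_names, modres = NULL) {
  raw_code <- toupper(trimws(raw_code))
  if (raw_code %in% names(.canonical_nt)) {
    code <- unname(.canonical_nt[[raw_code]])
    return(list(code = code, is_modified = !identical(code, raw_code)))
  }
  if (raw_code %in% names(.modified_nt_lookup)) {
    return(list(code = unname(.modified_nt_lookup[[raw_code]]),
                is_modified = TRUE))
  }
  if (!is.null(modres) && toupper(trimws(modres)) %in% names(.canonical_nt)) {
    return(list(code = unname(.canonical_nt[[toupper(trimws(modres))]]),
                is_modified = TRUE))
  }
  has_ring <- any(.rna_ring6 %in% atom_names)
  has_backbone <- any(c("P", "C1'") %in% atom_names)
  if (!has_ring && !has_backbone) {
    stop("residue '", raw_code,
         "' has neither base-ring nor backbone atoms; cannot assign a parent",
         call. = FALSE)
  }
  if ("N9" %in% atom_names) {
    warning("unknown nucleotide code '", raw_code,
            "': N9 present, assigning purine parent A", call. = FALSE)
    list(code = "A", is_modified = TRUE)
  } else {
    warning("unknown nucleotide code '", raw_code,
            "': assigning pyrimidine parent U", call. = FALSE)
    list(code = "U", is_modified = TRUE)
  }
}
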