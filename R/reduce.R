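## Coarse-graining: all-atom residues -> united-atom beads.

.named_atom_pos <- function(atoms) {
  # first occurrence wins (altloc duplicates already filtered upstream)
  keep <- !duplicated(atoms$name)
  m <- as.matrix(atoms[keep, c("x", "y", "z")])
  rownames(m) <- atoms$name[keep]
  m
}

.centroid_of <- function(pos, names_wanted, label, warn_missing = TRUE) {
  have <- intersect(names_wanted, rownames(pos))
  if (length(have) == 0L) return(NULL)
  if (warn_missing && length(have) < length(names_wanted))
    warning("bead ", label, " built from ", length(have), "/",
            length(names_wanted), " atoms", call. = FALSE)
  list(position = unname(colMeans(pos[have, , drop = FALSE])), atoms = have)
}

.bead <- function(code, role, position, axis, atoms,
                  normal = NULL, glyc = NULL) {
  list(type = paste(code, role, sep = "."), role = role,
       residue_code = code, position = unname(position),
       axis = unname(axis),
       normal = if (is.null(normal)) NULL else unname(normal),
       glyc = if (is.null(glyc)) NULL else unname(glyc),
       constituent_atoms = atoms)
}

#' Reduce a protein residue to united-atom beads
#'
#' Every residue gets a CA bead at the alpha-carbon position.  Residues
#' with a side chain get an SC1 bead at the unweighted centroid of the
#' proximal side-chain heavy atoms (out to the gamma layer), and the 13
#' largest residues additionally get an SC2 bead at the centroid of the
#' remaining distal atoms.  The CA bead axis points from CA towards SC1
#' (from N towards C for glycine); side-chain bead axes point from CA to
#' the bead.
#'
#' @param residue A residue record from an `rnp_structure` (protein kind).
#' @return A list of beads (possibly empty if CA is missing).
#' @export
reduce_protein_residue <- function(residue) {
  code <- residue$code
  if (!code %in% .amino3) {
    warning("unknown amino-acid code '", code, "': residue skipped",
            call. = FALSE)
    return(list())
  }
  pos <- .named_atom_pos(residue$atoms)
  if (!"CA" %in% rownames(pos)) {
    warning(code, " residue without CA skipped", call. = FALSE)
    return(list())
  }
  ca <- pos["CA", ]
  members <- .protein_bead_atoms[[code]]
  sc <- list()
  for (role in names(members)) {
    cen <- .centroid_of(pos, members[[role]], paste0(code, ".", role))
    if (is.null(cen)) {
      warning("no atoms available for ", code, ".", role, "; bead dropped",
              call. = FALSE)
      next
    }
    sc[[role]] <- cen
  }
  # CA reference axis
  ca_axis <- NULL
  if (!is.null(sc$SC1) && sum((sc$SC1$position - ca)^2) > 1e-18) {
    ca_axis <- .unit(sc$SC1$position - ca)
  } else if (all(c("N", "C") %in% rownames(pos))) {
    ca_axis <- .unit(pos["C", ] - pos["N", ])
  } else {
    warning(code, ": no side chain and no N/C for the CA axis; using +z",
            call. = FALSE)
    ca_axis <- c(0, 0, 1)
  }
  beads <- list(.bead(code, "CA", ca, ca_axis, "CA"))
  for (role in names(sc)) {
    beads[[length(beads) + 1L]] <-
      .bead(code, role, sc[[role]]$position,
            .unit(sc[[role]]$position - ca), sc[[role]]$atoms)
  }
  beads
}

#' Reduce an RNA nucleotide to united-atom beads
#'
#' The backbone is represented by a phosphate-group centroid (P, OP1,
#' OP2; absent for a 5'-terminal residue without phosphate) and a ribose
#' centroid (C1', C2', C3', C4', O4').  Pyrimidine bases get one ring
#' bead (PYR, six-ring centroid); purines get two (PUR6 six-ring and PUR5
#' five-ring centroids).  Base-ring beads carry an edge frame: the
#' oriented least-squares base-plane normal and the in-plane glycosidic
#' direction (C1' to N1 for pyrimidines, C1' to N9 for purines).  Axes:
#' base beads use the plane normal, P points to RIB, RIB points to the
#' base.
#'
#' @param residue A residue record (RNA kind, canonical code assigned).
#' @return A list of beads.
#' @export
reduce_rna_residue <- function(residue) {
  code <- residue$code
  if (!code %in% c("A", "C", "G", "U"))
    stop("residue rejected: no canonical parent base for '", code, "'",
         call. = FALSE)
  atoms <- residue$atoms
  # legacy O1P/O2P naming
  atoms$name[atoms$name == "O1P"] <- "OP1"
  atoms$name[atoms$name == "O2P"] <- "OP2"
  atoms$name <- gsub("\\*", "'", atoms$name)  # C1* style
  pos <- .named_atom_pos(atoms)
  purine <- code %in% .purines

  rib <- .centroid_of(pos, .rna_ribose, paste0(code, ".RIB"))
  ring_names <- if (purine) union(.rna_ring6, .rna_ring5) else .rna_ring6
  have_ring <- intersect(ring_names, rownames(pos))
  if (is.null(rib) && length(have_ring) == 0L)
    stop("residue rejected: no ribose and no base-ring atoms in ", code,
         call. = FALSE)

  beads <- list()
  base_beads <- list()
  normal <- glyc <- NULL
  if (length(have_ring) >= 3L) {
    ring6 <- intersect(.rna_ring6, rownames(pos))
    ring_pts <- pos[c(ring6, setdiff(have_ring, ring6)), , drop = FALSE]
    normal <- .plane_normal(ring_pts)
    ganchor <- if (purine) "N9" else "N1"
    if ("C1'" %in% rownames(pos) && ganchor %in% rownames(pos)) {
      gv <- pos[ganchor, ] - pos["C1'", ]
      gv <- gv - sum(gv * normal) * normal
      if (sum(gv^2) > 1e-18) glyc <- .unit(gv)
    }
    if (is.null(glyc))
      warning(code, ": glycosidic direction unavailable; edge term disabled ",
              "for this base", call. = FALSE)
    if (purine) {
      p6 <- .centroid_of(pos, .rna_ring6, paste0(code, ".PUR6"))
      p5 <- .centroid_of(pos, .rna_ring5, paste0(code, ".PUR5"))
      if (!is.null(p5))
        base_beads$PUR5 <- .bead(code, "PUR5", p5$position, normal,
                                 p5$atoms)
      if (!is.null(p6))
        base_beads$PUR6 <- .bead(code, "PUR6", p6$position, normal,
                                 p6$atoms, normal = normal, glyc = glyc)
    } else {
      py <- .centroid_of(pos, .rna_ring6, paste0(code, ".PYR"))
      if (!is.null(py))
        base_beads$PYR <- .bead(code, "PYR", py$position, normal,
                                py$atoms, normal = normal, glyc = glyc)
    }
  }
  base_ref <- if (!is.null(base_beads$PYR)) base_beads$PYR$position
              else if (!is.null(base_beads$PUR6)) base_beads$PUR6$position
              else NULL
  if ("P" %in% rownames(pos)) {
    pb <- .centroid_of(pos, .rna_phosphate, paste0(code, ".P"),
                       warn_missing = FALSE)
    target <- if (!is.null(rib)) rib$position else base_ref
    axis <- if (!is.null(target) && sum((target - pb$position)^2) > 1e-18)
      .unit(target - pb$position) else c(0, 0, 1)
    beads$P <- .bead(code, "P", pb$position, axis, pb$atoms)
  } else {
    warning(code, ": no phosphate (5'-terminal?); P bead omitted",
            call. = FALSE)
  }
  if (!is.null(rib)) {
    axis <- if (!is.null(base_ref) && sum((base_ref - rib$position)^2) > 1e-18)
      .unit(base_ref - rib$position) else c(0, 0, 1)
    beads$RIB <- .bead(code, "RIB", rib$position, axis, rib$atoms)
  }
  c(unname(beads), unname(base_beads))
}

.beads_to_side <- function(bead_list, resids, kind) {
  n <- length(bead_list)
  pos <- matrix(NA_real_, n, 3L)
  axis <- matrix(NA_real_, n, 3L)
  normal <- matrix(NA_real_, n, 3L)
  glyc <- matrix(NA_real_, n, 3L)
  type <- role <- code <- character(n)
  for (k in seq_len(n)) {
    b <- bead_list[[k]]
    pos[k, ] <- b$position; axis[k, ] <- b$axis
    if (!is.null(b$normal)) normal[k, ] <- b$normal
    if (!is.null(b$glyc)) glyc[k, ] <- b$glyc
    type[k] <- b$type; role[k] <- b$role; code[k] <- b$residue_code
  }
  list(kind = kind, type = type, role = role, code = code,
       resid = resids, pos = pos, axis = axis, normal = normal, glyc = glyc)
}

#' Reduce a parsed structure to a coarse-grained receptor/ligand complex
#'
#' Applies [reduce_protein_residue()] / [reduce_rna_residue()] to every
#' residue of the named chains.  Exactly one side must be protein and one
#' RNA (either may be the receptor).  Bead order is deterministic: chains
#' in the given order, residues in chain order, roles in their canonical
#' order.
#'
#' @param structure An `rnp_structure`.
#' @param receptor_chains,ligand_chains Chain ids for the two sides.
#' @param id Identifier stored on the complex.
#' @return An object of class `rnp_reduced` with `receptor` and `ligand`
#'   bead sides and their kinds.
#' @export
reduce_complex <- function(structure, receptor_chains, ligand_chains,
                           id = structure$source_id) {
  stopifnot(inherits(structure, "rnp_structure"))
  reduce_side <- function(chain_ids) {
    miss <- setdiff(chain_ids, names(structure$chains))
    if (length(miss))
      stop("chain id(s) not in structure: ", paste(miss, collapse = ", "),
           call. = FALSE)
    kinds <- unique(vapply(chain_ids,
                           function(cid) structure$chains[[cid]]$kind,
                           character(1)))
    if (length(kinds) != 1L || !kinds %in% c("protein", "rna"))
      stop("side chains must be uniformly protein or RNA (got: ",
           paste(kinds, collapse = ", "), ")", call. = FALSE)
    beads <- list(); resids <- character(0)
    for (cid in chain_ids) {
      for (r in structure$chains[[cid]]$residues) {
        rb <- if (kinds == "protein") reduce_protein_residue(r)
              else tryCatch(reduce_rna_residue(r), error = function(e) {
                warning(conditionMessage(e), call. = FALSE); list()
              })
        beads <- c(beads, rb)
        resids <- c(resids, rep(paste0(cid, ":", r$seq), length(rb)))
      }
    }
    if (length(beads) == 0L)
      stop("no beads could be built for chains ",
           paste(chain_ids, collapse = ","), call. = FALSE)
    .beads_to_side(beads, resids, kinds)
  }
  receptor <- reduce_side(receptor_chains)
  ligand <- reduce_side(ligand_chains)
  if (receptor$kind == ligand$kind)
    stop("receptor and ligand are both ", receptor$kind,
         "; one side must be protein and one RNA", call. = FALSE)
  structure(list(id = id, receptor = receptor, ligand = ligand,
                 receptor_kind = receptor$kind, ligand_kind = ligand$kind),
            class = "rnp_reduced")
}

.protein_side <- function(complex) {
  if (complex$receptor_kind == "protein") complex$receptor else complex$ligand
}

.rna_side <- function(complex) {
  if (complex$receptor_kind == "rna") complex$receptor else complex$ligand
}

# Apply a rigid motion (x -> R x + t) to one side's coordinates and frames
.transform_side <- function(side, R, t_vec) {
  side$pos <- side$pos %*% t(R) +
    matrix(t_vec, nrow(side$pos), 3L, byrow = TRUE)
  side$axis <- side$axis %*% t(R)
  side$normal <- side$normal %*% t(R)
  side$glyc <- side$glyc %*% t(R)
  side
}

#' Apply a rigid motion to a reduced complex
#'
#' Positions map as `R x + t`; axes and edge frames rotate.  With
#' `side = "ligand"` only the ligand moves (a docking pose); with
#' `side = "both"` the whole complex moves rigidly.
#'
#' @param complex An `rnp_reduced` complex.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 vector.
#' @param side `"both"`, `"ligand"` or `"receptor"`.
#' @return The transformed `rnp_reduced` complex.
#' @export
transform_complex <- function(complex, rotation, translation = c(0, 0, 0),
                              side = c("both", "ligand", "receptor")) {
  side <- match.arg(side)
  if (side %in% c("both", "receptor"))
    complex$receptor <- .transform_side(complex$receptor, rotation,
                                        translation)
  if (side %in% c("both", "ligand"))
    complex$ligand <- .transform_side(complex$ligand, rotation, translation)
  complex
}

#' Export a reduced complex as pseudo-PDB
#'
#' One ATOM record per bead with the bead role in the atom-name field and
#' the parent residue code in the residue field.  Non-standard: intended
#' for visual inspection only.
#'
#' @param complex An `rnp_reduced` complex.
#' @param file Optional output path.
#' @return The lines, invisibly.
#' @export
beads_as_pdb <- function(complex, file = NULL) {
  stopifnot(inherits(complex, "rnp_reduced"))
  out <- character(0); serial <- 0L
  emit <- function(side, chain) {
    for (k in seq_along(side$type)) {
      serial <<- serial + 1L
      role <- substr(gsub("'", "", side$role[k]), 1L, 4L)
      out <<- c(out, sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, role, substr(side$code[k], 1L, 3L), chain,
        serial %% 10000L, side$pos[k, 1], side$pos[k, 2], side$pos[k, 3]))
    }
  }
  emit(complex$receptor, "R")
  emit(complex$ligand, "L")
  out <- c(out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' @export
print.rnp_reduced <- function(x, ...) {
  cat("Reduced protein-RNA complex: ", x$id, "\n", sep = "")
  cat(sprintf("  receptor: %-7s %4d beads\n", x$receptor_kind,
              nrow(x$receptor$pos)))
  cat(sprintf("  ligand:   %-7s %4d beads\n", x$ligand_kind,
              nrow(x$ligand$pos)))
  invisible(x)
}
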