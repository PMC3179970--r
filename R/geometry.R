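## Vector and frame helpers ---------------------------------------------

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Least-squares plane normal of a point set, sign-aligned with the Newell
# normal of the points taken in their given order (deterministic
# orientation that is equivariant under proper rigid motions).
.plane_normal <- function(pts) {
  stopifnot(nrow(pts) >= 3L)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2L, ctr)
  sv <- svd(centered)
  n <- sv$v[, 3L]
  newell <- c(0, 0, 0)
  m <- nrow(pts)
  for (k in seq_len(m)) {
    a <- centered[k, ]; b <- centered[if (k == m) 1L else k + 1L, ]
    newell <- newell + .cross3(a, b)
  }
  if (sum(newell^2) > 1e-18 && sum(n * newell) < 0) n <- -n
  .unit(n)
}

## Contacts --------------------------------------------------------------

#' Angle between an RNA bead's axis and the direction to a protein bead
#'
#' The angular term measures the angle between the vector from the RNA
#' bead to the protein bead and the RNA bead's reference axis (the base
#' plane normal for ring beads, virtual-bond directions for backbone
#' beads).
#'
#' @param rna_bead,protein_bead Bead records (lists with `position`; the
#'   RNA bead must carry a unit `axis`).
#' @param scheme An [rnp_scheme()] for the bin index.
#' @return List with `angle` (degrees in `[0, 180]`) and 0-based `bin`.
#' @export
contact_angle <- function(rna_bead, protein_bead, scheme = rnp_scheme()) {
  v <- protein_bead$position - rna_bead$position
  if (sum(v^2) < 1e-18)
    stop("degenerate geometry: coincident bead positions", call. = FALSE)
  ct <- sum(.unit(v) * rna_bead$axis)
  theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  list(angle = theta, bin = bin_angle(theta, scheme))
}

#' Assign the nucleotide edge faced by a protein bead
#'
#' The protein bead direction is projected into the base plane and the
#' signed in-plane angle `phi` from the glycosidic direction (C1' to
#' N1/N9) is measured around the oriented base normal.  The three
#' Leontis-Westhof faces are fixed 120 degree wedges: Sugar for
#' `phi` in `[0, 120)`, Watson-Crick for `[120, 240)` (the face opposite
#' the sugar), Hoogsteen for `[240, 360)`.
#'
#' @param base_bead A PYR or PUR6 bead carrying `position`, `normal` and
#'   in-plane glycosidic direction `glyc`.
#' @param protein_bead A bead record with `position`.
#' @return One of `"WC"`, `"Hoogsteen"`, `"Sugar"`.
#' @export
assign_edge <- function(base_bead, protein_bead) {
  if (is.null(base_bead$normal) || is.null(base_bead$glyc) ||
      anyNA(base_bead$normal) || anyNA(base_bead$glyc))
    stop("base bead lacks an edge frame", call. = FALSE)
  v <- protein_bead$position - base_bead$position
  if (sqrt(sum(v^2)) < 0.1)
    stop("degenerate geometry: protein bead within 0.1 A of base centroid",
         call. = FALSE)
  n <- base_bead$normal
  vin <- v - sum(v * n) * n
  if (sum(vin^2) < 1e-18)
    stop("degenerate geometry: direction perpendicular to base plane",
         call. = FALSE)
  u <- .unit(vin)
  g <- base_bead$glyc
  phi <- atan2(sum(.cross3(g, u) * n), sum(g * u)) * 180 / pi
  if (phi < 0) phi <- phi + 360
  .edge_sector(phi)
}

# Wedge boundaries are module constants (degrees from the glycosidic
# direction, measured around the oriented base normal).
.edge_bounds <- c(Sugar = 0, WC = 120, Hoogsteen = 240)

.edge_sector <- function(phi) {
  ifelse(phi < 120, "Sugar", ifelse(phi < 240, "WC", "Hoogsteen"))
}

#' Enumerate protein-RNA bead contacts of a reduced complex
#'
#' All protein-bead x RNA-bead pairs with Euclidean distance strictly
#' below the scheme's cutoff.  Each contact carries its distance and
#' distance bin, the angle between the RNA bead axis and the direction to
#' the protein bead (with angle bin), and — for base-ring beads (PYR,
#' PUR6) — the nucleotide edge label.
#'
#' @param complex An `rnp_reduced` complex (see [reduce_complex()]).
#' @param scheme An [rnp_scheme()].
#' @return A data frame with one row per contact: `protein_type`,
#'   `rna_type`, `distance`, `dist_bin`, `angle`, `angle_bin`, `edge`
#'   (NA for non-base beads) plus bead indices `p_idx`, `r_idx`.
#' @export
find_contacts <- function(complex, scheme = rnp_scheme()) {
  stopifnot(inherits(complex, "rnp_reduced"))
  ps <- .protein_side(complex)
  rs <- .rna_side(complex)
  np <- nrow(ps$pos); nr <- nrow(rs$pos)
  empty <- data.frame(p_idx = integer(0), r_idx = integer(0),
                      protein_type = character(0), rna_type = character(0),
                      distance = numeric(0), dist_bin = integer(0),
                      angle = numeric(0), angle_bin = integer(0),
                      edge = character(0), stringsAsFactors = FALSE)
  if (np == 0L || nr == 0L) return(empty)
  d2 <- outer(rowSums(ps$pos^2), rowSums(rs$pos^2), "+") -
    2 * ps$pos %*% t(rs$pos)
  d2[d2 < 0] <- 0
  hit <- which(d2 < scheme$distance_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  pi_ <- hit[, 1L]; ri <- hit[, 2L]
  d <- sqrt(d2[hit])
  if (any(d < 1e-9))
    stop("degenerate geometry: coincident protein and RNA beads",
         call. = FALSE)
  v <- ps$pos[pi_, , drop = FALSE] - rs$pos[ri, , drop = FALSE]
  vn <- v / d
  ax <- rs$axis[ri, , drop = FALSE]
  ct <- pmin(1, pmax(-1, rowSums(vn * ax)))
  theta <- acos(ct) * 180 / pi

  edge <- rep(NA_character_, length(d))
  is_base <- rs$role[ri] %in% c("PYR", "PUR6") &
    !is.na(rs$glyc[ri, 1L]) & !is.na(rs$normal[ri, 1L])
  if (any(is_base)) {
    bb <- which(is_base)
    n <- rs$normal[ri[bb], , drop = FALSE]
    g <- rs$glyc[ri[bb], , drop = FALSE]
    vb <- v[bb, , drop = FALSE]
    vin <- vb - rowSums(vb * n) * n
    nin <- sqrt(rowSums(vin^2))
    ok <- nin > 1e-9
    u <- vin / pmax(nin, 1e-300)
    cx <- cbind(g[, 2] * u[, 3] - g[, 3] * u[, 2],
                g[, 3] * u[, 1] - g[, 1] * u[, 3],
                g[, 1] * u[, 2] - g[, 2] * u[, 1])
    phi <- atan2(rowSums(cx * n), rowSums(g * u)) * 180 / pi
    phi[phi < 0] <- phi[phi < 0] + 360
    edge[bb[ok]] <- .edge_sector(phi[ok])
  }
  data.frame(p_idx = as.integer(pi_), r_idx = as.integer(ri),
             protein_type = ps$type[pi_], rna_type = rs$type[ri],
             distance = d, dist_bin = bin_distance(d, scheme),
             angle = theta, angle_bin = bin_angle(theta, scheme),
             edge = edge, stringsAsFactors = FALSE)
}

## Superposition and RMSD -----------------------------------------------

#' Optimal receptor superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `mov` onto `ref`.
#'
#' @param ref,mov Matched n x 3 coordinate matrices, n >= 3, non-collinear.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and the residual `rmsd`; the transform acts as
#'   `x %*% t(rotation) + translation`.
#' @export
superpose_receptors <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3L || ncol(mov) != 3L)
    stop("ref and mov must be matched n x 3 matrices", call. = FALSE)
  if (nrow(ref) < 3L)
    stop("superposition needs at least 3 points", call. = FALSE)
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2L, cm); Q <- sweep(ref, 2L, cr)
  if (svd(Q)$d[2L] < 1e-8 * max(svd(Q)$d[1L], 1))
    stop("superposition is degenerate: points are collinear", call. = FALSE)
  H <- t(P) %*% Q
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fit <- mov %*% t(R) + matrix(t_vec, nrow(mov), 3L, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fit - ref)^2))))
}

#' Ligand RMSD after receptor superposition
#'
#' The distance between a docking model and the native complex: the model
#' receptor is optimally superposed onto the native receptor (Kabsch) and
#' the RMSD is taken over the ligand — all heavy atoms for all-atom
#' structures, bead positions for reduced complexes.  The computation mode
#' is recorded in the `"mode"` attribute.
#'
#' @param native,model Two `rnp_reduced` complexes, or two `rnp_structure`
#'   objects together with `receptor_chains` / `ligand_chains`.
#' @param receptor_chains,ligand_chains Chain ids (all-atom mode only).
#' @return Ligand RMSD in Angstrom.
#' @export
ligand_rmsd <- function(native, model, receptor_chains = NULL,
                        ligand_chains = NULL) {
  if (inherits(native, "rnp_reduced") && inherits(model, "rnp_reduced")) {
    .check_bead_match(native$receptor, model$receptor, "receptor")
    .check_bead_match(native$ligand, model$ligand, "ligand")
    tr <- superpose_receptors(native$receptor$pos, model$receptor$pos)
    lig <- model$ligand$pos %*% t(tr$rotation) +
      matrix(tr$translation, nrow(model$ligand$pos), 3L, byrow = TRUE)
    out <- sqrt(mean(rowSums((lig - native$ligand$pos)^2)))
    attr(out, "mode") <- "beads"
    return(out)
  }
  if (inherits(native, "rnp_structure") && inherits(model, "rnp_structure")) {
    if (is.null(receptor_chains) || is.null(ligand_chains))
      stop("receptor_chains and ligand_chains are required for all-atom RMSD",
           call. = FALSE)
    nr <- .chain_coords(native, receptor_chains)
    mr <- .chain_coords(model, receptor_chains)
    nl <- .chain_coords(native, ligand_chains)
    ml <- .chain_coords(model, ligand_chains)
    .check_atom_match(nr, mr, "receptor")
    .check_atom_match(nl, ml, "ligand")
    tr <- superpose_receptors(nr$xyz, mr$xyz)
    lig <- ml$xyz %*% t(tr$rotation) +
      matrix(tr$translation, nrow(ml$xyz), 3L, byrow = TRUE)
    out <- sqrt(mean(rowSums((lig - nl$xyz)^2)))
    attr(out, "mode") <- "heavy_atoms"
    return(out)
  }
  stop("native and model must both be rnp_reduced or both rnp_structure",
       call. = FALSE)
}

.check_bead_match <- function(a, b, what) {
  if (length(a$type) != length(b$type))
    stop(what, " bead counts differ between native and model", call. = FALSE)
  bad <- which(a$type != b$type)
  if (length(bad))
    stop(what, " bead mismatch at position ", bad[1L], ": native ",
         a$type[bad[1L]], " vs model ", b$type[bad[1L]], call. = FALSE)
}

.chain_coords <- function(structure, chain_ids) {
  miss <- setdiff(chain_ids, names(structure$chains))
  if (length(miss))
    stop("chain id(s) not in structure: ", paste(miss, collapse = ", "),
         call. = FALSE)
  labels <- character(0); xyz <- NULL
  for (cid in chain_ids) {
    for (r in structure$chains[[cid]]$residues) {
      labels <- c(labels, paste(cid, r$seq, r$code, r$atoms$name, sep = ":"))
      xyz <- rbind(xyz, as.matrix(r$atoms[, c("x", "y", "z")]))
    }
  }
  list(labels = labels, xyz = unname(xyz))
}

.check_atom_match <- function(a, b, what) {
  if (length(a$labels) != length(b$labels))
    stop(what, " atom counts differ between native and model", call. = FALSE)
  bad <- which(a$labels != b$labels)
  if (length(bad))
    stop(what, " atom mismatch at position ", bad[1L], ": native ",
         a$labels[bad[1L]], " vs model ", b$labels[bad[1L]], call. = FALSE)
}

## Rigid motion helpers (shared by the decoy sampler and tests) ----------

.quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

.mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    i <- k; j <- k %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[l, l] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

# ZYZ Euler angles (degrees) to rotation matrix
.euler_zyz <- function(a, b, g) {
  rz <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  ry <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3,
           byrow = TRUE)
  }
  rz(a) %*% ry(b) %*% rz(g)
}

# Uniform random rotation (for property tests and generic rigid motions)
.random_rotation <- function() {
  q <- stats::rnorm(4)
  .quat_to_mat(q / sqrt(sum(q^2)))
}
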