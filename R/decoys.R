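## Rigid-body pose sampling: geometric docking decoys used both as the
## DARS reference state and as test decoys.  Poses maximise geometric
## plausibility only (the ligand must touch the receptor and may not
## bury itself in it); no interaction energy is evaluated.

#' Sample a random rigid-body pose
#'
#' The rotation is drawn from the deterministic grid of ZYZ Euler-angle
#' triples at `rotation_step` degree intervals (uniformly over grid
#' cells); the translation places the ligand centroid uniformly in a
#' spherical shell around the receptor centroid, between the receptor
#' bounding radius and that radius plus `shell_width`.
#'
#' @param native An `rnp_reduced` complex providing the receptor geometry
#'   and the ligand centroid.
#' @param rotation_step Euler grid step in degrees; must divide 360.
#' @param shell_width Width of the translation shell in Angstrom.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `rnp_pose`: unit `quaternion`, `translation`
#'   (applied about the ligand centroid) and `provenance`.
#' @export
sample_pose <- function(native, rotation_step = 10, shell_width = 15,
                        seed = NULL) {
  stopifnot(inherits(native, "rnp_reduced"))
  if (rotation_step <= 0 || abs(360 / rotation_step -
                                round(360 / rotation_step)) > 1e-9)
    stop("rotation_step must divide 360", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ngrid <- as.integer(round(360 / rotation_step))
  eul <- (sample.int(ngrid, 3L, replace = TRUE) - 1L) * rotation_step
  R <- .euler_zyz(eul[1L], eul[2L], eul[3L])
  rc <- colMeans(native$receptor$pos)
  lc <- colMeans(native$ligand$pos)
  rb <- sqrt(max(rowSums(sweep(native$receptor$pos, 2L, rc)^2)))
  r <- (stats::runif(1) * ((rb + shell_width)^3 - rb^3) + rb^3)^(1 / 3)
  u <- .unit(stats::rnorm(3))
  target <- rc + r * u
  structure(list(quaternion = .mat_to_quat(R), euler = eul,
                 translation = target - lc,
                 provenance = sprintf("euler-grid step %g", rotation_step)),
            class = "rnp_pose")
}

#' Apply a pose to the ligand of a complex
#'
#' The ligand is rotated about its own centroid and then shifted by the
#' pose translation; the receptor is untouched.  An identity rotation
#' with zero translation leaves the complex unchanged.
#'
#' @param complex An `rnp_reduced` complex (the native).
#' @param pose An `rnp_pose`.
#' @return The posed `rnp_reduced` complex.
#' @export
apply_pose <- function(complex, pose) {
  stopifnot(inherits(complex, "rnp_reduced"), inherits(pose, "rnp_pose"))
  R <- .quat_to_mat(pose$quaternion)
  lc <- colMeans(complex$ligand$pos)
  t_eff <- lc - as.numeric(R %*% lc) + pose$translation
  complex$ligand <- .transform_side(complex$ligand, R, t_eff)
  complex
}

# positions-only pose application (filtering hot path)
.pose_ligand_pos <- function(pos, lc, R, translation) {
  pos %*% t(R) + matrix(lc - as.numeric(R %*% lc) + translation,
                        nrow(pos), 3L, byrow = TRUE)
}

#' Generate geometric docking decoys for a native complex
#'
#' Rejection sampling over random rigid poses ([sample_pose()]): a pose
#' is accepted when at least one receptor-ligand bead pair lies within
#' the contact cutoff (the molecules touch) and the fraction of ligand
#' beads closer than `clash_distance` to any receptor bead does not
#' exceed `max_clash_fraction`.  No energy is evaluated.
#'
#' With `near_native_fraction > 0` that share of poses is drawn instead
#' by perturbing the native pose (random rotation axis, normal rotation
#' and translation magnitudes), subject to the same filters.  Docking
#' decoy sets used for scoring benchmarks span ligand RMSDs from well
#' under 1 Angstrom up to tens of Angstrom; the mixture emulates that.
#' Reference decoys for the DARS state should keep the default 0
#' (geometric fit only, no knowledge of the native interface).
#'
#' @param native An `rnp_reduced` complex.
#' @param n Number of decoys to generate.
#' @param max_clash_fraction Maximum tolerated fraction of clashing
#'   ligand beads (default 0: no ligand bead may sit closer than
#'   `clash_distance` to any receptor bead).
#' @param seed Integer seed; the decoy set is bitwise reproducible given
#'   the seed and parameters.
#' @param rotation_step,shell_width Passed to [sample_pose()].
#' @param contact_cutoff Touching threshold in Angstrom (default 9, the
#'   scoring cutoff).
#' @param clash_distance Bead-centre clash threshold in Angstrom.  The
#'   default (`NULL`) adapts it per complex to the native's own closest
#'   receptor-ligand bead distance (capped at 95 percent of the contact
#'   cutoff): decoys may touch, but not pack tighter than the native
#'   does.  This emulates the per-complex repulsion adjustment docking
#'   programs need to keep rigid-body decoys physically realistic, since
#'   united-atom beads are centroids of several heavy atoms and modest
#'   bead-centre approaches already imply interpenetrating atoms.
#' @param max_attempts Hard cap on sampling attempts (default `1000 * n`).
#' @param near_native_fraction Share of poses drawn as perturbations of
#'   the native pose (default 0: purely random geometric poses).
#' @param near_rot_sd,near_trans_sd Perturbation scales: rotation angle
#'   (degrees) and per-axis translation (Angstrom) standard deviations.
#' @return An object of class `rnp_decoys`: the native, the accepted
#'   `poses` and the ligand RMSD of each decoy from the native.
#' @export
generate_decoys <- function(native, n, max_clash_fraction = 0,
                            seed = NULL, rotation_step = 10,
                            shell_width = 15, contact_cutoff = 9,
                            clash_distance = NULL, max_attempts = 1000 * n,
                            near_native_fraction = 0, near_rot_sd = 15,
                            near_trans_sd = 3) {
  stopifnot(inherits(native, "rnp_reduced"), n >= 1,
            near_native_fraction >= 0, near_native_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  rpos <- native$receptor$pos
  lpos <- native$ligand$pos
  lc <- colMeans(lpos)
  r2sum <- rowSums(rpos^2)
  if (is.null(clash_distance)) {
    d2n <- outer(r2sum, rowSums(lpos^2), "+") - 2 * rpos %*% t(lpos)
    clash_distance <- min(sqrt(max(min(d2n), 0)), 0.95 * contact_cutoff)
  }
  poses <- vector("list", n)
  rmsds <- numeric(n)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n) {
    if (attempts >= max_attempts)
      stop(sprintf(paste0("decoy generation exhausted %d attempts ",
                          "(acceptance rate %.2f%%); relax the clash ",
                          "filter or widen the shell"),
                   attempts, 100 * accepted / attempts), call. = FALSE)
    attempts <- attempts + 1L
    pose <- if (stats::runif(1) < near_native_fraction) {
      .perturb_pose(near_rot_sd, near_trans_sd)
    } else {
      sample_pose(native, rotation_step = rotation_step,
                  shell_width = shell_width)
    }
    newpos <- .pose_ligand_pos(lpos, lc, .quat_to_mat(pose$quaternion),
                               pose$translation)
    d2 <- outer(r2sum, rowSums(newpos^2), "+") - 2 * rpos %*% t(newpos)
    mind2 <- apply(d2, 2L, min)  # per ligand bead
    if (min(mind2) >= contact_cutoff^2) next          # not touching
    clash_frac <- mean(mind2 < clash_distance^2)
    if (clash_frac > max_clash_fraction) next
    accepted <- accepted + 1L
    poses[[accepted]] <- pose
    rmsds[accepted] <- sqrt(mean(rowSums((newpos - lpos)^2)))
  }
  structure(list(native = native, poses = poses, ligand_rmsds = rmsds,
                 n = n, seed = seed,
                 params = list(max_clash_fraction = max_clash_fraction,
                               rotation_step = rotation_step,
                               shell_width = shell_width,
                               contact_cutoff = contact_cutoff,
                               clash_distance = clash_distance,
                               near_native_fraction = near_native_fraction,
                               near_rot_sd = near_rot_sd,
                               near_trans_sd = near_trans_sd)),
            class = "rnp_decoys")
}

# small random perturbation of the native pose (rotation about the
# ligand centroid + translation)
.perturb_pose <- function(rot_sd, trans_sd) {
  axis <- .unit(stats::rnorm(3))
  angle <- stats::rnorm(1, 0, rot_sd) * pi / 180
  q <- c(cos(angle / 2), sin(angle / 2) * axis)
  if (q[1] < 0) q <- -q
  structure(list(quaternion = q, euler = NULL,
                 translation = stats::rnorm(3, 0, trans_sd),
                 provenance = "native-perturbation"),
            class = "rnp_pose")
}

#' Materialise one decoy of a decoy set as a complex
#'
#' @param decoys An `rnp_decoys` set.
#' @param k Decoy index.
#' @return The posed `rnp_reduced` complex.
#' @export
decoy_complex <- function(decoys, k) {
  stopifnot(inherits(decoys, "rnp_decoys"), k >= 1, k <= decoys$n)
  out <- apply_pose(decoys$native, decoys$poses[[k]])
  out$id <- paste0(out$id, "_decoy", k)
  out
}

#' @export
print.rnp_decoys <- function(x, ...) {
  cat(sprintf("Decoy set: %d rigid-body poses of '%s'\n", x$n, x$native$id))
  cat(sprintf("  ligand RMSD from native: %.1f - %.1f A (median %.1f)\n",
              min(x$ligand_rmsds), max(x$ligand_rmsds),
              stats::median(x$ligand_rmsds)))
  invisible(x)
}

# Summed contact-count arrays over a whole decoy set (no per-decoy
# retention; used for the DARS reference).
.decoy_count_arrays <- function(decoys, scheme) {
  total <- .count_arrays(scheme)
  for (k in seq_len(decoys$n)) {
    contacts <- find_contacts(decoy_complex(decoys, k), scheme)
    if (nrow(contacts) == 0L) next
    arr <- .tabulate_contacts(contacts, scheme)
    total$dist <- total$dist + arr$dist
    total$angle <- total$angle + arr$angle
    total$edge <- total$edge + arr$edge
  }
  total
}
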