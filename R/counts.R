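## Binned contact statistics, reference states and reverse-Boltzmann
## energies.

.count_arrays <- function(scheme) {
  tp <- rnp_bead_types()
  dn_p <- tp$protein; dn_r <- tp$rna
  nd <- scheme$n_dist_bins; na <- scheme$n_angle_bins
  list(
    dist = array(0, c(length(dn_p), length(dn_r), nd),
                 dimnames = list(dn_p, dn_r, paste0("d", seq_len(nd) - 1L))),
    angle = array(0, c(length(dn_p), length(dn_r), na),
                  dimnames = list(dn_p, dn_r, paste0("a", seq_len(na) - 1L))),
    edge = array(0, c(length(dn_p), length(dn_r), 3L),
                 dimnames = list(dn_p, dn_r, scheme$edge_labels))
  )
}

.tabulate_contacts <- function(contacts, scheme) {
  arr <- .count_arrays(scheme)
  if (nrow(contacts) == 0L) return(arr)
  ptypes <- dimnames(arr$dist)[[1L]]; rtypes <- dimnames(arr$dist)[[2L]]
  pi_ <- match(contacts$protein_type, ptypes)
  ri <- match(contacts$rna_type, rtypes)
  if (anyNA(pi_))
    stop("unknown protein bead type: ",
         contacts$protein_type[which(is.na(pi_))[1L]], call. = FALSE)
  if (anyNA(ri))
    stop("unknown RNA bead type: ",
         contacts$rna_type[which(is.na(ri))[1L]], call. = FALSE)
  np <- length(ptypes); nr <- length(rtypes)
  dI <- pi_ + np * (ri - 1L) + np * nr * contacts$dist_bin
  arr$dist[] <- tabulate(dI, np * nr * scheme$n_dist_bins)
  aI <- pi_ + np * (ri - 1L) + np * nr * contacts$angle_bin
  arr$angle[] <- tabulate(aI, np * nr * scheme$n_angle_bins)
  has_edge <- !is.na(contacts$edge)
  if (any(has_edge)) {
    ei <- match(contacts$edge[has_edge], scheme$edge_labels) - 1L
    eI <- pi_[has_edge] + np * (ri[has_edge] - 1L) + np * nr * ei
    arr$edge[] <- tabulate(eI, np * nr * 3L)
  }
  arr
}

.bead_type_tally <- function(complex) {
  tp <- rnp_bead_types()
  ps <- .protein_side(complex); rs <- .rna_side(complex)
  list(protein = table(factor(ps$type, levels = tp$protein)),
       rna = table(factor(rs$type, levels = tp$rna)))
}

#' Accumulate binned contact counts over training complexes
#'
#' Every contact of every complex increments its (protein type, RNA type,
#' distance bin), (protein type, RNA type, angle bin) and — for base-ring
#' beads — (protein type, RNA type, edge) cells, so each contact
#' contributes once to the distance and angle tables and at most once to
#' the edge table.  Per-complex sub-counts are retained for leave-one-out
#' training.
#'
#' @param complexes A list of `rnp_reduced` complexes (names, or their
#'   `id` fields, become complex ids).
#' @param scheme An [rnp_scheme()].
#' @return An object of class `rnp_counts` with `dist`, `angle`, `edge`
#'   count arrays, per-complex sub-counts and bead-type tallies.
#' @export
count_contacts <- function(complexes, scheme = rnp_scheme()) {
  if (inherits(complexes, "rnp_reduced")) complexes <- list(complexes)
  stopifnot(length(complexes) >= 1L)
  ids <- names(complexes)
  if (is.null(ids))
    ids <- vapply(complexes, function(x) as.character(x$id), character(1))
  ids <- make.unique(ids)
  total <- .count_arrays(scheme)
  per <- vector("list", length(complexes)); names(per) <- ids
  for (k in seq_along(complexes)) {
    contacts <- find_contacts(complexes[[k]], scheme)
    if (nrow(contacts) == 0L)
      warning("complex '", ids[k], "' has no protein-RNA contacts",
              call. = FALSE)
    arr <- .tabulate_contacts(contacts, scheme)
    total$dist <- total$dist + arr$dist
    total$angle <- total$angle + arr$angle
    total$edge <- total$edge + arr$edge
    per[[k]] <- c(arr, list(beads = .bead_type_tally(complexes[[k]])))
  }
  structure(list(dist = total$dist, angle = total$angle, edge = total$edge,
                 per_complex = per, n_complexes = length(complexes),
                 scheme = scheme),
            class = "rnp_counts")
}

#' @export
print.rnp_counts <- function(x, ...) {
  cat(sprintf(paste0("Contact counts over %d complex(es): ",
                     "%d distance, %d angle, %d edge observations\n"),
              x$n_complexes, sum(x$dist), sum(x$angle), sum(x$edge)))
  invisible(x)
}

#' Mole fractions of bead types in a training set
#'
#' The fraction of protein beads of each protein type, and of RNA beads
#' of each RNA type, pooled over all training complexes.  Each vector
#' sums to one.
#'
#' @param complexes A list of `rnp_reduced` complexes, or an `rnp_counts`
#'   object (uses its retained bead tallies).
#' @return List with numeric vectors `protein` (length 52) and `rna`
#'   (length 14).
#' @export
mole_fractions <- function(complexes) {
  if (inherits(complexes, "rnp_counts")) {
    tallies <- lapply(complexes$per_complex, `[[`, "beads")
  } else {
    if (inherits(complexes, "rnp_reduced")) complexes <- list(complexes)
    tallies <- lapply(complexes, .bead_type_tally)
  }
  prot <- Reduce(`+`, lapply(tallies, function(t) as.numeric(t$protein)))
  rna <- Reduce(`+`, lapply(tallies, function(t) as.numeric(t$rna)))
  if (sum(prot) == 0 || sum(rna) == 0)
    stop("training set has zero beads on one side", call. = FALSE)
  tp <- rnp_bead_types()
  list(protein = stats::setNames(prot / sum(prot), tp$protein),
       rna = stats::setNames(rna / sum(rna), tp$rna))
}

#' Quasi-chemical expected counts
#'
#' The mole-fraction reference state: the expected count in cell
#' `(i, j, bin)` is `X_i * X_j * N_obs(bin)`, where `N_obs(bin)` is the
#' total observed count in that bin of that term.  Because the mole
#' fractions each sum to one, expected counts are conserved per bin:
#' `sum_ij N_exp(i,j,bin) = N_obs(bin)`.
#'
#' @param counts An `rnp_counts` object.
#' @param X Mole fractions as returned by [mole_fractions()]; computed
#'   from `counts` when omitted.
#' @return An object of class `rnp_reference` (kind `"quasi"`).
#' @export
quasi_expected <- function(counts, X = mole_fractions(counts)) {
  stopifnot(inherits(counts, "rnp_counts"))
  xx <- outer(X$protein, X$rna)
  expand <- function(arr) {
    out <- arr
    tot <- apply(arr, 3L, sum)
    for (b in seq_along(tot)) out[, , b] <- xx * tot[b]
    out
  }
  structure(list(dist = expand(counts$dist), angle = expand(counts$angle),
                 edge = expand(counts$edge), kind = "quasi",
                 X_protein = X$protein, X_rna = X$rna,
                 scheme = counts$scheme),
            class = "rnp_reference")
}

#' Decoys-as-reference-state expected counts
#'
#' Contact counts measured on geometric docking decoys of the training
#' complexes, normalised term-wise so the grand total of expected counts
#' matches the grand total of native counts:
#' `N_exp = N_decoy * (sum N_obs / sum N_decoy)`.
#'
#' @param decoy_counts `rnp_counts` accumulated over decoys.
#' @param native_counts `rnp_counts` over the native training complexes.
#' @return An object of class `rnp_reference` (kind `"dars"`).
#' @export
dars_expected <- function(decoy_counts, native_counts) {
  stopifnot(inherits(decoy_counts, "rnp_counts"),
            inherits(native_counts, "rnp_counts"))
  out <- list(kind = "dars", scheme = native_counts$scheme, scale = c())
  for (term in c("dist", "angle", "edge")) {
    nd <- sum(decoy_counts[[term]]); nn <- sum(native_counts[[term]])
    if (nd == 0 && nn > 0)
      stop("no decoy contacts for the ", term,
           " term; generate larger decoy sets", call. = FALSE)
    s <- if (nd == 0) 0 else nn / nd
    out[[term]] <- decoy_counts[[term]] * s
    out$scale[term] <- s
  }
  structure(out, class = "rnp_reference")
}

#' Reverse-Boltzmann energy table
#'
#' Converts observed and expected contact counts to interaction energies
#' cell by cell: `eps(i,j,bin) = -RT * log((N_obs + a) / (N_exp + a))`,
#' with pseudocount `a` keeping every cell finite.  Enriched contacts
#' (observed above expectation) get negative energies.
#'
#' @param obs An `rnp_counts` object.
#' @param exp An `rnp_reference` object of matching shape.
#' @param RT Energy scale (default 1: unitless scores; only rankings and
#'   correlations are used downstream).
#' @param pseudocount Additive pseudocount `a >= 0`; must be positive if
#'   any cell of `obs` or `exp` is zero.
#' @param clash_distance,clash_penalty Steric-clash term parameters:
#'   every bead pair closer than `clash_distance` (Angstrom) adds
#'   `clash_penalty * RT` to the score.
#' @param provenance Free-text training description stored on the table.
#' @return An object of class `rnp_table` holding the three energy arrays
#'   and the scoring parameters.
#' @export
energy_table <- function(obs, exp, RT = 1, pseudocount = 1,
                         clash_distance = 3, clash_penalty = 1,
                         provenance = "") {
  stopifnot(inherits(obs, "rnp_counts"), inherits(exp, "rnp_reference"),
            RT > 0, pseudocount >= 0)
  energies <- list()
  for (term in c("dist", "angle", "edge")) {
    o <- obs[[term]]; e <- exp[[term]]
    stopifnot(identical(dim(o), dim(e)))
    if (pseudocount == 0 && (any(o == 0) || any(e == 0)))
      stop("pseudocount 0 requires strictly positive counts in every cell",
           call. = FALSE)
    energies[[term]] <- -RT * log((o + pseudocount) / (e + pseudocount))
  }
  structure(list(energies = energies, RT = RT, pseudocount = pseudocount,
                 clash_distance = clash_distance,
                 clash_penalty = clash_penalty,
                 reference = exp$kind, scheme = obs$scheme,
                 provenance = provenance),
            class = "rnp_table")
}

#' @export
print.rnp_table <- function(x, ...) {
  cat("Reverse-Boltzmann energy table (", x$reference, " reference)\n",
      sep = "")
  cat(sprintf("  RT = %g, pseudocount = %g, clash: < %g A -> +%g per pair\n",
              x$RT, x$pseudocount, x$clash_distance, x$clash_penalty))
  for (term in c("dist", "angle", "edge"))
    cat(sprintf("  %-5s term: energies in [%.3f, %.3f]\n", term,
                min(x$energies[[term]]), max(x$energies[[term]])))
  if (nzchar(x$provenance)) cat("  trained on: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Score a complex with the four-term function
#'
#' `E = Ed + Ea + Es + Ep` with equal weights: the distance term sums the
#' distance-bin energies over all contacts, the angle term the angle-bin
#' energies, the site (edge) term the edge energies over base-ring
#' contacts, and the clash penalty adds `clash_penalty * RT` per bead
#' pair closer than `clash_distance`.  Lower is better.
#'
#' @param complex An `rnp_reduced` complex.
#' @param table An `rnp_table` (or a fitted [rnp_potential()] object).
#' @param scheme Binning scheme; defaults to the table's.
#' @return A list of class `rnp_score`: `Ed`, `Ea`, `Es`, `Ep`, total
#'   `E`, `n_contacts` and `n_clashes`.
#' @export
score_complex <- function(complex, table, scheme = NULL) {
  if (inherits(table, "rnp_potential")) table <- table$table
  stopifnot(inherits(table, "rnp_table"))
  if (is.null(scheme)) scheme <- table$scheme
  if (scheme$n_dist_bins != dim(table$energies$dist)[3L] ||
      scheme$n_angle_bins != dim(table$energies$angle)[3L])
    stop("binning scheme is inconsistent with the energy table",
         call. = FALSE)
  contacts <- find_contacts(complex, scheme)
  if (nrow(contacts) == 0L) {
    out <- list(Ed = 0, Ea = 0, Es = 0, Ep = 0, E = 0,
                n_contacts = 0L, n_clashes = 0L)
    class(out) <- "rnp_score"
    return(out)
  }
  ptypes <- dimnames(table$energies$dist)[[1L]]
  rtypes <- dimnames(table$energies$dist)[[2L]]
  pi_ <- match(contacts$protein_type, ptypes)
  ri <- match(contacts$rna_type, rtypes)
  if (anyNA(pi_))
    stop("bead type not in table: ",
         contacts$protein_type[which(is.na(pi_))[1L]], call. = FALSE)
  if (anyNA(ri))
    stop("bead type not in table: ",
         contacts$rna_type[which(is.na(ri))[1L]], call. = FALSE)
  np <- length(ptypes); nr <- length(rtypes)
  Ed <- sum(table$energies$dist[pi_ + np * (ri - 1L) +
                                  np * nr * contacts$dist_bin])
  Ea <- sum(table$energies$angle[pi_ + np * (ri - 1L) +
                                   np * nr * contacts$angle_bin])
  he <- !is.na(contacts$edge)
  Es <- if (any(he)) {
    ei <- match(contacts$edge[he], scheme$edge_labels) - 1L
    sum(table$energies$edge[pi_[he] + np * (ri[he] - 1L) + np * nr * ei])
  } else 0
  n_clashes <- sum(contacts$distance < table$clash_distance)
  Ep <- table$clash_penalty * table$RT * n_clashes
  out <- list(Ed = Ed, Ea = Ea, Es = Es, Ep = Ep, E = Ed + Ea + Es + Ep,
              n_contacts = nrow(contacts), n_clashes = as.integer(n_clashes))
  class(out) <- "rnp_score"
  out
}

#' @export
print.rnp_score <- function(x, ...) {
  cat(sprintf(paste0("E = %.4f  (Ed %.4f + Ea %.4f + Es %.4f + Ep %.4f;",
                     " %d contacts, %d clashes)\n"),
              x$E, x$Ed, x$Ea, x$Es, x$Ep, x$n_contacts, x$n_clashes))
  invisible(x)
}
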