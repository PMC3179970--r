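## The user-facing model: train a statistical potential on a set of
## protein-RNA complexes, then score and rank docking decoys with it.

#' Fit a protein-RNA statistical potential
#'
#' Accumulates binned contact counts over the training complexes,
#' builds the chosen reference state — `"quasi"` (quasi-chemical: mole
#' fractions of bead types) or `"dars"` (decoys as the reference state:
#' contact frequencies measured on geometric docking decoys generated
#' internally for each training complex) — and inverts the
#' observed/expected ratio into energies by reverse Boltzmann statistics.
#' The fitted object scores complexes with the four-term function
#' `E = Ed + Ea + Es + Ep` via [predict.rnp_potential()].
#'
#' @param complexes A list of `rnp_reduced` complexes (see
#'   [reduce_complex()]), or a single complex.
#' @param reference `"dars"` or `"quasi"`.
#' @param scheme An [rnp_scheme()].
#' @param RT,pseudocount,clash_distance,clash_penalty Passed to
#'   [energy_table()].
#' @param decoys_per_complex Number of reference decoys per training
#'   complex (DARS only; default 200).
#' @param seed Integer seed for the decoy generator (DARS only).
#' @param max_clash_fraction Clash filter for reference decoys (the
#'   decoy generator's own bead-overlap threshold applies; see
#'   [generate_decoys()]).
#' @param loo If `TRUE`, precompute leave-one-out tables (see
#'   [loo_tables()]).
#' @return An object of class `rnp_potential` with components `table`
#'   (the [energy_table()]), `counts`, `reference`, `mole_fractions` and
#'   training metadata.
#' @examples
#' natives <- lapply(1:3, function(s) {
#'   s3 <- make_toy_complex(6, 3, seed = s)
#'   reduce_complex(s3, receptor_chains = "A", ligand_chains = "B")
#' })
#' fit <- rnp_potential(natives, reference = "quasi")
#' predict(fit, natives[[1]])
#' @export
rnp_potential <- function(complexes, reference = c("dars", "quasi"),
                          scheme = rnp_scheme(), RT = 1, pseudocount = 1,
                          clash_distance = 3, clash_penalty = 1,
                          decoys_per_complex = 200, seed = 1,
                          max_clash_fraction = 0, loo = FALSE) {
  reference <- match.arg(reference)
  if (inherits(complexes, "rnp_reduced")) complexes <- list(complexes)
  counts <- count_contacts(complexes, scheme)
  X <- mole_fractions(counts)
  ids <- names(counts$per_complex)

  decoy_per <- NULL
  if (reference == "dars") {
    set.seed(seed)
    decoy_per <- vector("list", length(complexes))
    names(decoy_per) <- ids
    for (k in seq_along(complexes)) {
      dec <- generate_decoys(complexes[[k]], decoys_per_complex,
                             max_clash_fraction = max_clash_fraction,
                             contact_cutoff = scheme$distance_cutoff)
      decoy_per[[k]] <- .decoy_count_arrays(dec, scheme)
    }
    ref <- .dars_from_arrays(Reduce(.add_arrays, decoy_per), counts, scheme)
  } else {
    ref <- quasi_expected(counts, X)
  }
  prov <- sprintf("%s reference, %d complex(es)%s", reference,
                  length(complexes),
                  if (reference == "dars")
                    sprintf(", %d decoys/complex (seed %d)",
                            decoys_per_complex, seed) else "")
  table <- energy_table(counts, ref, RT = RT, pseudocount = pseudocount,
                        clash_distance = clash_distance,
                        clash_penalty = clash_penalty, provenance = prov)
  fit <- structure(list(table = table, counts = counts, reference = ref,
                        mole_fractions = X, reference_kind = reference,
                        scheme = scheme, complex_ids = ids,
                        decoy_per = decoy_per,
                        params = list(RT = RT, pseudocount = pseudocount,
                                      clash_distance = clash_distance,
                                      clash_penalty = clash_penalty,
                                      decoys_per_complex = decoys_per_complex,
                                      seed = seed,
                                      max_clash_fraction =
                                        max_clash_fraction),
                        loo = NULL, call = match.call()),
                   class = "rnp_potential")
  if (loo) fit$loo <- loo_tables(fit)
  fit
}

.add_arrays <- function(a, b) {
  list(dist = a$dist + b$dist, angle = a$angle + b$angle,
       edge = a$edge + b$edge)
}

.dars_from_arrays <- function(decoy_arrays, native_counts, scheme) {
  dc <- structure(c(decoy_arrays,
                    list(per_complex = list(), n_complexes = NA_integer_,
                         scheme = scheme)),
                  class = "rnp_counts")
  dars_expected(dc, native_counts)
}

# counts with one complex's contribution removed
.counts_without <- function(counts, id) {
  sub <- counts$per_complex[[id]]
  if (is.null(sub)) stop("no per-complex counts for '", id, "'",
                         call. = FALSE)
  out <- counts
  out$dist <- counts$dist - sub$dist
  out$angle <- counts$angle - sub$angle
  out$edge <- counts$edge - sub$edge
  out$per_complex <- counts$per_complex[setdiff(names(counts$per_complex),
                                                id)]
  out$n_complexes <- counts$n_complexes - 1L
  out
}

#' Leave-one-out potential tables
#'
#' For each training complex, an energy table retrained with that
#' complex's contribution removed — its contacts, its beads (mole
#' fractions) and, for DARS, its reference decoys — so a complex is
#' never scored by a potential that saw it.
#'
#' @param fit A fitted [rnp_potential()].
#' @return A named list of `rnp_table` objects, one per training complex.
#' @export
loo_tables <- function(fit) {
  stopifnot(inherits(fit, "rnp_potential"))
  if (!is.null(fit$loo)) return(fit$loo)
  ids <- fit$complex_ids
  if (length(ids) < 2L)
    stop("leave-one-out needs at least two training complexes",
         call. = FALSE)
  p <- fit$params
  out <- vector("list", length(ids)); names(out) <- ids
  for (id in ids) {
    counts_m <- .counts_without(fit$counts, id)
    X_m <- mole_fractions(counts_m)
    ref_m <- if (fit$reference_kind == "quasi") {
      quasi_expected(counts_m, X_m)
    } else {
      dec <- Reduce(.add_arrays, fit$decoy_per[setdiff(ids, id)])
      .dars_from_arrays(dec, counts_m, fit$scheme)
    }
    out[[id]] <- energy_table(counts_m, ref_m, RT = p$RT,
                              pseudocount = p$pseudocount,
                              clash_distance = p$clash_distance,
                              clash_penalty = p$clash_penalty,
                              provenance = sprintf("LOO (left out: %s)", id))
  }
  out
}

#' @export
print.rnp_potential <- function(x, ...) {
  cat("Protein-RNA statistical potential (",
      toupper(x$reference_kind), " reference)\n", sep = "")
  cat(sprintf("  trained on %d complex(es): %s\n",
              length(x$complex_ids),
              paste(utils::head(x$complex_ids, 5L), collapse = ", ")))
  cat(sprintf("  contacts: %d (distance term), scheme: %d x 1 A bins, ",
              sum(x$counts$dist), x$scheme$n_dist_bins))
  cat(sprintf("%d x %g deg bins, 3 edges\n", x$scheme$n_angle_bins,
              x$scheme$angle_bin_width))
  print(x$table)
  invisible(x)
}

#' @export
summary.rnp_potential <- function(object, ...) {
  en <- object$table$energies
  term_stats <- t(vapply(en, function(e)
    c(min = min(e), median = stats::median(e), max = max(e),
      negative_cells = sum(e < 0)), numeric(4)))
  best <- which(en$dist == min(en$dist), arr.ind = TRUE)[1L, ]
  dn <- dimnames(en$dist)
  out <- list(reference = object$reference_kind,
              n_complexes = length(object$complex_ids),
              n_contacts = sum(object$counts$dist),
              term_stats = term_stats,
              strongest_pair = sprintf("%s - %s (%s)", dn[[1L]][best[1L]],
                                       dn[[2L]][best[2L]], dn[[3L]][best[3L]]))
  class(out) <- "summary.rnp_potential"
  out
}

#' @export
print.summary.rnp_potential <- function(x, ...) {
  cat(sprintf("%s potential, %d complexes, %d contacts\n",
              toupper(x$reference), x$n_complexes, x$n_contacts))
  print(round(x$term_stats, 3))
  cat("most favourable distance cell:", x$strongest_pair, "\n")
  invisible(x)
}

#' Extract the energy tables of a fitted potential
#'
#' @param object A fitted [rnp_potential()].
#' @param ... Unused.
#' @return A long data frame with columns `term`, `protein_type`,
#'   `rna_type`, `bin`, `n_obs`, `n_exp` and `energy`.
#' @export
coef.rnp_potential <- function(object, ...) {
  out <- NULL
  for (term in c("dist", "angle", "edge")) {
    e <- object$table$energies[[term]]
    dn <- dimnames(e)
    g <- expand.grid(protein_type = dn[[1L]], rna_type = dn[[2L]],
                     bin = dn[[3L]], stringsAsFactors = FALSE)
    g$term <- term
    g$n_obs <- as.vector(object$counts[[term]])
    g$n_exp <- as.vector(object$reference[[term]])
    g$energy <- as.vector(e)
    out <- rbind(out, g[, c("term", "protein_type", "rna_type", "bin",
                            "n_obs", "n_exp", "energy")])
  }
  out
}

#' Score complexes with a fitted potential
#'
#' @param object A fitted [rnp_potential()].
#' @param newdata An `rnp_reduced` complex or a list of them.
#' @param table Optional replacement `rnp_table` (e.g. a leave-one-out
#'   table from [loo_tables()]).
#' @param ... Unused.
#' @return A data frame with one row per complex: `id`, `n_contacts`,
#'   `n_clashes`, the term energies `Ed`, `Ea`, `Es`, `Ep` and total `E`
#'   (lower is better).
#' @export
predict.rnp_potential <- function(object, newdata, table = NULL, ...) {
  if (inherits(newdata, "rnp_reduced")) newdata <- list(newdata)
  tab <- if (is.null(table)) object$table else table
  ids <- names(newdata)
  if (is.null(ids))
    ids <- vapply(newdata, function(x) as.character(x$id), character(1))
  rows <- lapply(seq_along(newdata), function(k) {
    s <- score_complex(newdata[[k]], tab, object$scheme)
    data.frame(id = ids[k], n_contacts = s$n_contacts,
               n_clashes = s$n_clashes, Ed = s$Ed, Ea = s$Ea, Es = s$Es,
               Ep = s$Ep, E = s$E, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot energy profiles of a fitted potential
#'
#' Distance- (or angle-) dependence of the energy for selected bead-type
#' pairs; by default the six pairs with the deepest minima.
#'
#' @param x A fitted [rnp_potential()].
#' @param term `"dist"` or `"angle"`.
#' @param pairs Optional 2-column character matrix (protein type, RNA
#'   type) selecting profiles.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rnp_potential <- function(x, term = c("dist", "angle"), pairs = NULL,
                               ...) {
  term <- match.arg(term)
  e <- x$table$energies[[term]]
  if (is.null(pairs)) {
    flat <- apply(e, c(1L, 2L), min)
    ord <- order(flat)[seq_len(min(6L, length(flat)))]
    idx <- arrayInd(ord, dim(flat))
    pairs <- cbind(dimnames(e)[[1L]][idx[, 1L]],
                   dimnames(e)[[2L]][idx[, 2L]])
  }
  w <- if (term == "dist") x$scheme$distance_bin_width
       else x$scheme$angle_bin_width
  mids <- (seq_len(dim(e)[3L]) - 0.5) * w
  prof <- sapply(seq_len(nrow(pairs)),
                 function(k) e[pairs[k, 1L], pairs[k, 2L], ])
  graphics::matplot(mids, prof, type = "b", pch = 16, lty = 1,
                    xlab = if (term == "dist") "distance [A]"
                           else "angle [deg]",
                    ylab = "energy [RT]", ...)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  graphics::legend("bottomright", legend = paste(pairs[, 1L], pairs[, 2L],
                                                 sep = " - "),
                   col = seq_len(nrow(pairs)), pch = 16, cex = 0.7,
                   bty = "n")
  invisible(x)
}

## Serialization ---------------------------------------------------------

#' Write a fitted potential to a TSV file
#'
#' One row per (term, protein type, RNA type, bin) cell with observed
#' count, expected count and energy, preceded by a commented JSON header
#' recording the scheme and scoring parameters.  Values are written with
#' 17 significant digits, so [read_potential()] round-trips bit-exactly.
#'
#' @param fit A fitted [rnp_potential()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_potential <- function(fit, file) {
  stopifnot(inherits(fit, "rnp_potential"))
  hdr <- jsonlite::toJSON(list(
    format = "rnpscore-potential-1",
    reference = fit$reference_kind,
    RT = fit$params$RT, pseudocount = fit$params$pseudocount,
    clash_distance = fit$params$clash_distance,
    clash_penalty = fit$params$clash_penalty,
    distance_cutoff = fit$scheme$distance_cutoff,
    distance_bin_width = fit$scheme$distance_bin_width,
    angle_bin_width = fit$scheme$angle_bin_width,
    provenance = fit$table$provenance), auto_unbox = TRUE, digits = NA)
  df <- coef(fit)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  writeLines(paste("term", "protein_type", "rna_type", "bin_label",
                   "n_obs", "n_exp", "energy", sep = "\t"), con)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%.17g\t%.17g\t%.17g",
                     df$term, df$protein_type, df$rna_type, df$bin,
                     df$n_obs, df$n_exp, df$energy), con)
  invisible(file)
}

#' Read a potential written by [write_potential()]
#'
#' Reconstructs a scoring-capable `rnp_potential` object (energy tables,
#' counts, reference and parameters; per-complex training detail is not
#' serialized).  The binning scheme is validated against the cell count.
#'
#' @param file Path to a potential TSV.
#' @return An object of class `rnp_potential`.
#' @export
read_potential <- function(file) {
  lines <- readLines(file)
  if (!startsWith(lines[1L], "# "))
    stop("missing JSON header line", call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1L]))
  if (!identical(hdr$format, "rnpscore-potential-1"))
    stop("not an rnpscore potential file", call. = FALSE)
  df <- utils::read.table(text = lines[-1L], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  scheme <- rnp_scheme(distance_cutoff = hdr$distance_cutoff,
                       distance_bin_width = hdr$distance_bin_width,
                       angle_bin_width = hdr$angle_bin_width)
  arrs <- .count_arrays(scheme)
  energies <- arrs; reference <- arrs
  for (term in names(arrs)) {
    sub <- df[df$term == term, ]
    dn <- dimnames(arrs[[term]])
    idx <- cbind(match(sub$protein_type, dn[[1L]]),
                 match(sub$rna_type, dn[[2L]]),
                 match(sub$bin_label, dn[[3L]]))
    if (anyNA(idx) || nrow(sub) != length(arrs[[term]]))
      stop("potential file is inconsistent with the ", term,
           " binning scheme", call. = FALSE)
    arrs[[term]][idx] <- sub$n_obs
    reference[[term]][idx] <- sub$n_exp
    energies[[term]][idx] <- sub$energy
  }
  counts <- structure(c(arrs, list(per_complex = list(),
                                   n_complexes = NA_integer_,
                                   scheme = scheme)),
                      class = "rnp_counts")
  ref <- structure(c(reference, list(kind = hdr$reference,
                                     scheme = scheme)),
                   class = "rnp_reference")
  table <- structure(list(energies = energies, RT = hdr$RT,
                          pseudocount = hdr$pseudocount,
                          clash_distance = hdr$clash_distance,
                          clash_penalty = hdr$clash_penalty,
                          reference = hdr$reference, scheme = scheme,
                          provenance = hdr$provenance),
                     class = "rnp_table")
  structure(list(table = table, counts = counts, reference = ref,
                 mole_fractions = NULL, reference_kind = hdr$reference,
                 scheme = scheme, complex_ids = character(0),
                 decoy_per = NULL,
                 params = list(RT = hdr$RT, pseudocount = hdr$pseudocount,
                               clash_distance = hdr$clash_distance,
                               clash_penalty = hdr$clash_penalty),
                 loo = NULL, call = NULL),
            class = "rnp_potential")
}
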