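## Greedy RMSD clustering of best-scored decoys and score-RMSD
## evaluation.

#' Greedy clustering of the best-scored decoys
#'
#' Restricts to the `top_n` best-scored (lowest-energy) decoys, then
#' iterates the greedy rule on their pairwise ligand-RMSD matrix: the row
#' with the largest number of RMSD values below the cutoff (ties broken
#' by the lower decoy index) seeds a cluster containing itself and those
#' neighbours, the members are removed, and the process repeats until no
#' remaining row has a neighbour within the cutoff.  Clusters are
#' ordered by size (ties by representative score), and each cluster's
#' representative is its lowest-energy member.
#'
#' @param scores Numeric decoy scores (lower is better).
#' @param rmsd_matrix Symmetric pairwise ligand-RMSD matrix with zero
#'   diagonal, in the same order as `scores`.
#' @param top_n Number of best-scored decoys to cluster (default 100;
#'   capped at the number of decoys with a warning).
#' @param cutoff Neighbourhood RMSD cutoff in Angstrom (default 5).
#' @param ids Optional decoy identifiers (default `1:n` as characters).
#' @return An object of class `rnp_clusters`: `clusters` (list of member
#'   id vectors, largest first), `representatives`, `sizes`, plus the
#'   parameters and a `relaxed` flag (FALSE here).
#' @export
cluster_decoys <- function(scores, rmsd_matrix, top_n = 100, cutoff = 5,
                           ids = NULL) {
  n <- length(scores)
  if (n < 2L) stop("clustering needs at least 2 decoys", call. = FALSE)
  rmsd_matrix <- as.matrix(rmsd_matrix)
  if (!all(dim(rmsd_matrix) == n))
    stop("rmsd_matrix dimensions do not match scores", call. = FALSE)
  if (max(abs(rmsd_matrix - t(rmsd_matrix))) > 1e-6 ||
      max(abs(diag(rmsd_matrix))) > 1e-6)
    stop("rmsd_matrix must be symmetric with zero diagonal", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (top_n > n) {
    warning("top_n capped at the number of decoys (", n, ")",
            call. = FALSE)
    top_n <- n
  }
  sel <- order(scores)[seq_len(top_n)]
  sel <- sort(sel)                       # deterministic row indexing
  active <- rep(TRUE, length(sel))
  adj <- rmsd_matrix[sel, sel, drop = FALSE] < cutoff
  diag(adj) <- FALSE

  clusters <- list()
  while (any(active)) {
    neigh <- rowSums(adj[, active, drop = FALSE]) * active
    m <- max(neigh)
    if (m < 1) break
    row <- which(neigh == m)[1L]        # tie -> lowest index
    members <- c(row, which(adj[row, ] & active))
    members <- sort(unique(members))
    clusters[[length(clusters) + 1L]] <- sel[members]
    active[members] <- FALSE
    adj[members, ] <- FALSE
    adj[, members] <- FALSE
  }
  .finish_clusters(clusters, scores, ids, top_n, cutoff, relaxed = FALSE)
}

.finish_clusters <- function(clusters, scores, ids, top_n, cutoff,
                             relaxed) {
  if (length(clusters)) {
    rep_idx <- vapply(clusters, function(m) m[which.min(scores[m])],
                      integer(1))
    sizes <- lengths(clusters)
    ord <- order(-sizes, scores[rep_idx])
    clusters <- clusters[ord]; rep_idx <- rep_idx[ord]; sizes <- sizes[ord]
  } else {
    rep_idx <- integer(0); sizes <- integer(0)
  }
  structure(list(clusters = lapply(clusters, function(m) ids[m]),
                 members = clusters,
                 representatives = ids[rep_idx],
                 representative_scores = scores[rep_idx],
                 sizes = sizes, top_n = top_n, cutoff = cutoff,
                 relaxed = relaxed, n_clusters = length(clusters)),
            class = "rnp_clusters")
}

#' Relaxed clustering fallback
#'
#' When primary clustering (default 100 best-scored decoys, 5 Angstrom
#' cutoff) finds no clusters, re-cluster with relaxed settings: 200
#' best-scored decoys and a 10 Angstrom cutoff, flagging the result as
#' relaxed.  If the primary result already has clusters it is returned
#' unchanged.
#'
#' @param result The primary `rnp_clusters` result.
#' @param scores,rmsd_matrix,ids As in [cluster_decoys()].
#' @param top_n,cutoff Relaxed parameters (defaults 200 and 10).
#' @return An `rnp_clusters` object; `relaxed = TRUE` when the fallback
#'   ran (possibly still empty).
#' @export
relaxed_clustering_fallback <- function(result, scores, rmsd_matrix,
                                        ids = NULL, top_n = 200,
                                        cutoff = 10) {
  stopifnot(inherits(result, "rnp_clusters"))
  if (result$n_clusters > 0L) return(result)
  out <- cluster_decoys(scores, rmsd_matrix, top_n = top_n,
                        cutoff = cutoff, ids = ids)
  out$relaxed <- TRUE
  out
}

#' @export
print.rnp_clusters <- function(x, ...) {
  cat(sprintf("Greedy decoy clustering (top %d, cutoff %g A)%s\n",
              x$top_n, x$cutoff,
              if (x$relaxed) " [relaxed fallback]" else ""))
  if (x$n_clusters == 0L) {
    cat("  no clusters found\n")
    return(invisible(x))
  }
  show <- seq_len(min(3L, x$n_clusters))
  for (k in show)
    cat(sprintf("  cluster %d: %d members, representative %s (E = %.3f)\n",
                k, x$sizes[k], x$representatives[k],
                x$representative_scores[k]))
  if (x$n_clusters > 3L)
    cat("  (", x$n_clusters - 3L, " smaller cluster(s) not shown)\n",
        sep = "")
  invisible(x)
}

#' Score-RMSD correlation report
#'
#' Pearson correlation between decoy scores and ligand RMSDs, restricted
#' to decoys below each RMSD threshold (defaults 5, 10 and 20 Angstrom),
#' with the standard error of the correlation coefficient
#' `SE = sqrt((1 - r^2) / (n - 2))`.  Thresholds with fewer than three
#' decoys, or with zero variance in either vector, are reported as
#' undefined (`NA`).
#'
#' @param scores,rmsds Equal-length paired vectors.
#' @param thresholds RMSD thresholds in Angstrom.
#' @param native_score Optional score of the native structure; adds a
#'   `native_rank` attribute (see [rank_native()]).
#' @return A data frame of class `rnp_eval` with columns `threshold`,
#'   `n_below`, `pearson_r`, `std_error`.
#' @export
correlation_report <- function(scores, rmsds, thresholds = c(5, 10, 20),
                               native_score = NULL) {
  stopifnot(length(scores) == length(rmsds))
  rows <- lapply(thresholds, function(th) {
    sel <- which(rmsds < th)
    n <- length(sel)
    if (n < 3L || stats::sd(scores[sel]) == 0 || stats::sd(rmsds[sel]) == 0)
      return(data.frame(threshold = th, n_below = n,
                        pearson_r = NA_real_, std_error = NA_real_))
    r <- stats::cor(scores[sel], rmsds[sel])
    data.frame(threshold = th, n_below = n, pearson_r = r,
               std_error = sqrt((1 - r^2) / (n - 2)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rnp_eval", "data.frame")
  if (!is.null(native_score))
    attr(out, "native_rank") <- rank_native(native_score, scores)
  out
}

#' @export
print.rnp_eval <- function(x, ...) {
  cat("Score-RMSD correlation\n")
  for (k in seq_len(nrow(x))) {
    if (is.na(x$pearson_r[k]))
      cat(sprintf("  < %2g A: n = %4d, r undefined\n", x$threshold[k],
                  x$n_below[k]))
    else
      cat(sprintf("  < %2g A: n = %4d, r = %+.3f (SE %.3f)\n",
                  x$threshold[k], x$n_below[k], x$pearson_r[k],
                  x$std_error[k]))
  }
  nr <- attr(x, "native_rank")
  if (!is.null(nr)) cat("  native rank:", nr, "\n")
  invisible(x)
}

#' Rank of the native structure among decoys
#'
#' One plus the number of decoys scoring strictly better (lower) than
#' the native; rank 1 means the native beats every decoy.
#'
#' @param native_score Score of the native structure.
#' @param decoy_scores Decoy scores from the same table and scheme.
#' @return Integer rank (1 = best).
#' @export
rank_native <- function(native_score, decoy_scores) {
  1L + sum(decoy_scores < native_score)
}
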