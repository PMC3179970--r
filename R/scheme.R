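#' Contact binning scheme
#'
#' Defines how protein-RNA bead contacts are discretised: a hard distance
#' cutoff (a contact exists when the bead-bead distance is strictly below
#' it), half-open 1 Angstrom distance bins, 20 degree angle bins over
#' [0, 180] (the last bin closed so 180 is representable), and the three
#' nucleotide-edge labels of the Leontis-Westhof faces.
#'
#' @param distance_cutoff Contact cutoff in Angstrom (default 9).
#' @param distance_bin_width Distance bin width in Angstrom (default 1);
#'   the cutoff must be an integer multiple of it.
#' @param angle_bin_width Angle bin width in degrees (default 20); must
#'   divide 180.
#' @return An object of class `rnp_scheme`.
#' @examples
#' s <- rnp_scheme()
#' s$n_dist_bins   # 9
#' @export
rnp_scheme <- function(distance_cutoff = 9, distance_bin_width = 1,
                       angle_bin_width = 20) {
  stopifnot(distance_cutoff > 0, distance_bin_width > 0, angle_bin_width > 0)
  nd <- distance_cutoff / distance_bin_width
  if (abs(nd - round(nd)) > 1e-9)
    stop("distance_cutoff must be an integer multiple of distance_bin_width",
         call. = FALSE)
  na <- 180 / angle_bin_width
  if (abs(na - round(na)) > 1e-9)
    stop("angle_bin_width must divide 180", call. = FALSE)
  structure(list(distance_cutoff = distance_cutoff,
                 distance_bin_width = distance_bin_width,
                 angle_bin_width = angle_bin_width,
                 n_dist_bins = as.integer(round(nd)),
                 n_angle_bins = as.integer(round(na)),
                 edge_labels = c("WC", "Hoogsteen", "Sugar")),
            class = "rnp_scheme")
}

#' @export
print.rnp_scheme <- function(x, ...) {
  cat("Contact binning scheme\n")
  cat(sprintf("  distance: cutoff %g A (strict <), %d bins of %g A\n",
              x$distance_cutoff, x$n_dist_bins, x$distance_bin_width))
  cat(sprintf("  angle:    %d bins of %g deg over [0, 180]\n",
              x$n_angle_bins, x$angle_bin_width))
  cat("  edges:    ", paste(x$edge_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Distance bin index
#'
#' Half-open bins `[k*w, (k+1)*w)`; indices run from 0.
#'
#' @param r Distance(s) in Angstrom, `0 <= r < cutoff`.
#' @param scheme An [rnp_scheme()].
#' @return Integer bin indices (0-based).
#' @export
bin_distance <- function(r, scheme = rnp_scheme()) {
  if (any(r < 0 | r >= scheme$distance_cutoff))
    stop("distance out of range [0, cutoff)", call. = FALSE)
  as.integer(floor(r / scheme$distance_bin_width))
}

#' Angle bin index
#'
#' Half-open bins except the last, which is closed so that 180 degrees maps
#' to the final bin.
#'
#' @param theta Angle(s) in degrees within [0, 180].
#' @param scheme An [rnp_scheme()].
#' @return Integer bin indices (0-based).
#' @export
bin_angle <- function(theta, scheme = rnp_scheme()) {
  if (any(theta < -1e-9 | theta > 180 + 1e-9))
    stop("angle out of range [0, 180]", call. = FALSE)
  pmin(as.integer(floor(theta / scheme$angle_bin_width)),
       scheme$n_angle_bins - 1L)
}
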