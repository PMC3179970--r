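## Synthetic all-atom complexes and planted-signal training sets.
##
## Fixtures use idealised geometry — a regular alpha-helical protein with
## templated side-chain offsets, and a regular RNA helix with exactly
## planar base rings — so bead centroids, plane normals and edge frames
## are analytically checkable.

.rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# side-chain layer depth from the remoteness letter of the atom name
.sc_layer <- c(B = 1, G = 2, D = 3, E = 4, Z = 5, H = 6)

.protein_residue_atoms <- function(code, ca, t_hat, n_hat, b_hat) {
  sc_names <- unlist(.protein_bead_atoms[[code]], use.names = FALSE)
  nm <- c("N", "CA", "C", "O", sc_names)
  pos <- matrix(0, length(nm), 3L)
  pos[1L, ] <- ca - 1.2 * t_hat + 0.5 * b_hat
  pos[2L, ] <- ca
  pos[3L, ] <- ca + 1.2 * t_hat + 0.5 * b_hat
  pos[4L, ] <- ca + 1.4 * t_hat + 0.6 * n_hat + 1.0 * b_hat
  if (length(sc_names)) {
    for (k in seq_along(sc_names)) {
      a <- sc_names[k]
      layer <- .sc_layer[[substr(a, 2L, 2L)]]
      digit <- suppressWarnings(as.integer(substr(a, nchar(a), nchar(a))))
      lateral <- if (is.na(digit)) 0 else (digit - 1.5) * 0.8
      pos[4L + k, ] <- ca + (0.8 + 0.7 * layer) * n_hat +
        lateral * b_hat + 0.2 * layer * t_hat
    }
  }
  data.frame(name = nm, element = substr(nm, 1L, 1L),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             hetero = FALSE, stringsAsFactors = FALSE)
}

# local nucleotide template: C1' at origin, base extending towards +x,
# ring exactly in the z = 0 plane
.nt_template <- function(code) {
  purine <- code %in% .purines
  pts <- list()
  if (!purine) {
    ctr <- c(2.88, 0)
    ang <- c(N1 = 180, C2 = 240, N3 = 300, C4 = 0, C5 = 60, C6 = 120)
    for (a in names(ang))
      pts[[a]] <- c(ctr + 1.4 * c(cos(ang[[a]] * pi / 180),
                                  sin(ang[[a]] * pi / 180)), 0)
  } else {
    rp <- 1.4 / (2 * sin(36 * pi / 180))       # pentagon circumradius
    pc <- c(1.48 + rp, 0)
    pang <- c(N9 = 180, C4 = 108, C5 = 36, N7 = -36, C8 = -108)
    for (a in names(pang))
      pts[[a]] <- c(pc + rp * c(cos(pang[[a]] * pi / 180),
                                sin(pang[[a]] * pi / 180)), 0)
    # hexagon fused on the C4-C5 edge, on the far side of the pentagon
    m <- (pts$C4[1:2] + pts$C5[1:2]) / 2
    dir <- m - pc; dir <- dir / sqrt(sum(dir^2))
    hc <- m + (1.4 * sqrt(3) / 2) * dir
    a4 <- atan2(pts$C4[2] - hc[2], pts$C4[1] - hc[1]) * 180 / pi
    a5 <- atan2(pts$C5[2] - hc[2], pts$C5[1] - hc[1]) * 180 / pi
    delta <- ((a5 - a4 + 540) %% 360) - 180
    step <- -sign(delta) * 60
    for (k in 1:4) {
      nm <- c("N3", "C2", "N1", "C6")[k]
      aa <- (a4 + step * k) * pi / 180
      pts[[nm]] <- c(hc + 1.4 * c(cos(aa), sin(aa)), 0)
    }
  }
  pts[["C1'"]] <- c(0, 0, 0)
  pts[["O4'"]] <- c(-0.7, -1.2, 0.3)
  pts[["C2'"]] <- c(-0.8, 1.1, 0.4)
  pts[["C3'"]] <- c(-2.1, 0.7, 0.6)
  pts[["C4'"]] <- c(-2.0, -0.8, 0.5)
  pts[["P"]] <- c(-3.3, -1.5, 1.2)
  pts[["OP1"]] <- c(-4.1, -2.5, 1.5)
  pts[["OP2"]] <- c(-4.3, -0.6, 1.7)
  do.call(rbind, pts)
}

.rna_residue_atoms <- function(code, index, radius = 6, twist = 8,
                               rise = 3.0) {
  tmpl <- .nt_template(code)
  flipped <- tmpl %*% t(.rot_z(180))        # base points towards the axis
  flipped[, 1L] <- flipped[, 1L] + radius
  placed <- flipped %*% t(.rot_z(twist * index))
  placed[, 3L] <- placed[, 3L] + rise * index
  nm <- rownames(tmpl)
  rownames(placed) <- NULL
  data.frame(name = nm, element = substr(nm, 1L, 1L),
             x = placed[, 1], y = placed[, 2], z = placed[, 3],
             hetero = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a synthetic all-atom protein-RNA complex
#'
#' The protein is an ideal alpha helix (2.3 Angstrom radius, 1.5 rise,
#' 100 degrees per residue) with side-chain atoms at templated offsets
#' along the outward helix normal; the RNA is a gently twisted regular
#' helix (8 degrees twist, 3.0 rise per nucleotide) whose backbone keeps
#' facing the protein, with exactly planar base rings.  The
#' two molecules are placed with a defined interface: the minimum
#' heavy-atom gap is adjusted to `gap` (within [4, 6] Angstrom).
#' Deterministic given the seed.
#'
#' Like real protein-RNA interfaces, the random sequences are
#' compositionally biased at the binding site: helix positions whose
#' side chains face the RNA draw from a set of RNA-binding residue types
#' (arginine, lysine and polar amides/hydroxyls), the remaining
#' positions from the other types.  This gives independently generated
#' complexes a shared, learnable contact preference.
#'
#' @param n_protein_residues,n_rna_residues Chain lengths (>= 1).
#' @param seed Integer seed (drives the random sequences).
#' @param protein_sequence,rna_sequence Optional explicit sequences
#'   (three-letter amino acid codes; A/C/G/U), overriding the random
#'   ones (and the interface bias).
#' @param gap Target interface gap in Angstrom.
#' @param interface_bias Draw interface-facing residues from the
#'   RNA-binding set (default `TRUE`).
#' @return An `rnp_structure` with a protein chain "A" and an RNA chain
#'   "B", writable as valid PDB via [write_pdb()].
#' @export
make_toy_complex <- function(n_protein_residues, n_rna_residues, seed = 1,
                             protein_sequence = NULL, rna_sequence = NULL,
                             gap = 5, interface_bias = TRUE) {
  stopifnot(n_protein_residues >= 1, n_rna_residues >= 1,
            gap >= 4, gap <= 6)
  set.seed(seed)

  helix_ca <- function(i) {
    c(2.3 * cos(100 * i * pi / 180), 2.3 * sin(100 * i * pi / 180), 1.5 * i)
  }
  frames <- lapply(seq_len(n_protein_residues), function(i) {
    ca <- helix_ca(i)
    t_hat <- .unit(helix_ca(i + 0.1) - helix_ca(i - 0.1))
    n_hat <- .unit(c(ca[1], ca[2], 0))
    b_hat <- .unit(.cross3(t_hat, n_hat))
    list(ca = ca, t_hat = t_hat, n_hat = .unit(.cross3(b_hat, t_hat)),
         b_hat = b_hat)
  })
  if (is.null(protein_sequence)) {
    binding <- c("ARG", "LYS", "SER", "GLN")
    protein_sequence <- character(n_protein_residues)
    for (i in seq_len(n_protein_residues)) {
      # the RNA is placed along +x; side chains facing it get binding types
      facing <- interface_bias && frames[[i]]$n_hat[1L] > cos(75 * pi / 180)
      pool <- if (facing) binding else setdiff(.amino3, binding)
      protein_sequence[i] <- sample(pool, 1L)
    }
  }
  if (is.null(rna_sequence))
    rna_sequence <- sample(c("A", "C", "G", "U"), n_rna_residues,
                           replace = TRUE)
  stopifnot(length(protein_sequence) == n_protein_residues,
            length(rna_sequence) == n_rna_residues)

  prot_res <- vector("list", n_protein_residues)
  for (i in seq_len(n_protein_residues)) {
    f <- frames[[i]]
    code <- protein_sequence[i]
    prot_res[[i]] <- list(raw_code = code, code = code, chain = "A",
                          seq = as.character(i), icode = " ",
                          is_modified = FALSE, kind = "protein",
                          atoms = .protein_residue_atoms(code, f$ca,
                                                         f$t_hat, f$n_hat,
                                                         f$b_hat))
  }
  rna_res <- vector("list", n_rna_residues)
  for (j in seq_len(n_rna_residues)) {
    code <- rna_sequence[j]
    rna_res[[j]] <- list(raw_code = code, code = code, chain = "B",
                         seq = as.character(j), icode = " ",
                         is_modified = FALSE, kind = "rna",
                         atoms = .rna_residue_atoms(code, j - 1L))
  }

  # slide the RNA along +x until the interface gap reaches the target
  pxyz <- do.call(rbind, lapply(prot_res, function(r)
    as.matrix(r$atoms[, c("x", "y", "z")])))
  rxyz <- do.call(rbind, lapply(rna_res, function(r)
    as.matrix(r$atoms[, c("x", "y", "z")])))
  offset <- max(pxyz[, 1]) - min(rxyz[, 1]) + 30
  for (it in 1:60) {
    d2 <- outer(rowSums(pxyz^2), rowSums(sweep(rxyz, 2L,
                c(-offset, 0, 0))^2), "+") -
      2 * pxyz %*% t(sweep(rxyz, 2L, c(-offset, 0, 0)))
    m <- sqrt(max(min(d2), 0))
    if (abs(m - gap) < 0.05) break
    offset <- offset - (m - gap)
  }
  for (j in seq_len(n_rna_residues))
    rna_res[[j]]$atoms$x <- rna_res[[j]]$atoms$x + offset

  structure(list(source_id = sprintf("toy_p%d_r%d_s%d", n_protein_residues,
                                     n_rna_residues, seed),
                 chains = list(A = list(id = "A", kind = "protein",
                                        residues = prot_res),
                               B = list(id = "B", kind = "rna",
                                        residues = rna_res))),
            class = "rnp_structure")
}

.split_type <- function(type) {
  parts <- strsplit(type, ".", fixed = TRUE)
  list(code = vapply(parts, `[[`, character(1), 1L),
       role = vapply(parts, `[[`, character(1), 2L))
}

#' Generate a planted-signal training set of reduced complexes
#'
#' A test scaffold for reference-state recovery: synthetic reduced
#' complexes built from isolated "contact units" — one protein bead and
#' one RNA bead placed at a controlled distance on a coarse 3D grid
#' (grid spacing exceeds the contact cutoff, so every unit contributes
#' exactly one contact).  Background units cover a reduced universe of
#' bead-type pairs with distances drawn from the volume-element null
#' density (`p(r)` proportional to `r^2` below the cutoff) — the same
#' distance marginal that random geometric placement produces — so the
#' planted `(protein type, RNA type, distance bin)` cell is the only
#' systematic deviation from a null contact pattern.  That cell receives
#' enough extra units that its count is `enrichment` times the mean
#' background count of the other type pairs in the same distance bin.
#'
#' @param n_complexes Number of complexes.
#' @param planted_pair Character vector `c(protein type, rna type)`, e.g.
#'   `c("ARG.SC2", "G.PUR6")`.
#' @param planted_bin 0-based distance bin of the planted signal.
#' @param enrichment Target count ratio (> 1) of the planted cell over
#'   the mean same-bin background cell; realised within ~20 percent.
#' @param seed Integer seed; generation is bitwise reproducible.
#' @param n_protein_types,n_rna_types Size of the background type
#'   universe (planted types included).
#' @param units_per_pair Background units per type pair per complex.
#' @param spacing Grid spacing in Angstrom (must exceed the cutoff plus
#'   the largest intra-unit distance).
#' @param scheme An [rnp_scheme()].
#' @return A list of `rnp_reduced` complexes with a `"planted"` attribute
#'   recording the planted cell and the type universe.
#' @export
make_planted_training_set <- function(n_complexes,
                                      planted_pair = c("ARG.SC2", "G.PUR6"),
                                      planted_bin = 4, enrichment = 5,
                                      seed = 1, n_protein_types = 8,
                                      n_rna_types = 6, units_per_pair = 4,
                                      spacing = 20, scheme = rnp_scheme()) {
  stopifnot(n_complexes >= 1, enrichment > 1,
            planted_bin >= 0, planted_bin < scheme$n_dist_bins)
  tp <- rnp_bead_types()
  if (!planted_pair[1L] %in% tp$protein)
    stop("planted protein type '", planted_pair[1L],
         "' is not in the bead enumeration", call. = FALSE)
  if (!planted_pair[2L] %in% tp$rna)
    stop("planted RNA type '", planted_pair[2L],
         "' is not in the bead enumeration", call. = FALSE)
  if (spacing <= scheme$distance_cutoff + scheme$distance_cutoff)
    stop("geometrically unsatisfiable: grid spacing must exceed twice the ",
         "contact cutoff", call. = FALSE)
  pick_universe <- function(all, planted, n) {
    others <- setdiff(all, planted)
    if (n - 1L > length(others)) stop("type universe too large",
                                      call. = FALSE)
    idx <- unique(round(seq(1L, length(others), length.out = n - 1L)))
    c(planted, others[idx])
  }
  up <- pick_universe(tp$protein, planted_pair[1L], n_protein_types)
  ur <- pick_universe(tp$rna, planted_pair[2L], n_rna_types)

  set.seed(seed)
  nd <- scheme$n_dist_bins
  w <- scheme$distance_bin_width
  cutoff <- scheme$distance_cutoff
  # weight of the planted bin under the volume-element null density
  w_bin <- (((planted_bin + 1) * w)^3 - (planted_bin * w)^3) / cutoff^3
  mean_bg_cell <- units_per_pair * n_complexes * w_bin
  # the planted pair's background avoids the planted bin (see below), so
  # the planted cell is populated by the extra units alone
  extras_total <- max(1L, as.integer(round(enrichment * mean_bg_cell)))
  extras <- rep(extras_total %/% n_complexes, n_complexes)
  rem <- extras_total %% n_complexes
  if (rem > 0) extras[seq_len(rem)] <- extras[seq_len(rem)] + 1L

  out <- vector("list", n_complexes)
  for (k in seq_len(n_complexes)) {
    pairs <- expand.grid(p = up, r = ur, rep = seq_len(units_per_pair),
                         stringsAsFactors = FALSE)
    n_bg <- nrow(pairs)
    d_bg <- cutoff * stats::runif(n_bg)^(1 / 3)          # p(r) ~ r^2
    # keep the planted pair's background out of the planted bin so the
    # planted-cell count is set deterministically by the extras
    is_pl_pair <- pairs$p == planted_pair[1L] & pairs$r == planted_pair[2L]
    for (rep_ in 1:50) {
      redo <- is_pl_pair & bin_distance(pmin(d_bg, cutoff - 1e-9),
                                        scheme) == planted_bin
      if (!any(redo)) break
      d_bg[redo] <- cutoff * stats::runif(sum(redo))^(1 / 3)
    }
    d_pl <- (planted_bin + stats::runif(extras[k])) * w
    ptype <- c(pairs$p, rep(planted_pair[1L], extras[k]))
    rtype <- c(pairs$r, rep(planted_pair[2L], extras[k]))
    n_units <- length(ptype)
    d <- pmax(c(d_bg, d_pl), 0.15)

    g <- ceiling(n_units^(1 / 3))
    grid <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g),
                                  z = seq_len(g))) * spacing
    gpts <- grid[sample.int(nrow(grid), n_units), , drop = FALSE]
    dirs <- matrix(stats::rnorm(3 * n_units), n_units, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ppos <- gpts + dirs * d
    rpos <- gpts

    st <- .split_type(rtype)
    axis_r <- matrix(stats::rnorm(3 * n_units), n_units, 3L)
    axis_r <- axis_r / sqrt(rowSums(axis_r^2))
    normal <- glyc <- matrix(NA_real_, n_units, 3L)
    is_base <- st$role %in% c("PYR", "PUR6")
    if (any(is_base)) {
      normal[is_base, ] <- axis_r[is_base, , drop = FALSE]
      raw <- matrix(stats::rnorm(3 * sum(is_base)), sum(is_base), 3L)
      proj <- raw - rowSums(raw * normal[is_base, , drop = FALSE]) *
        normal[is_base, , drop = FALSE]
      glyc[is_base, ] <- proj / sqrt(rowSums(proj^2))
    }
    stp <- .split_type(ptype)
    axis_p <- matrix(stats::rnorm(3 * n_units), n_units, 3L)
    axis_p <- axis_p / sqrt(rowSums(axis_p^2))

    receptor <- list(kind = "protein", type = ptype, role = stp$role,
                     code = stp$code,
                     resid = paste0("P:", seq_len(n_units)),
                     pos = ppos, axis = axis_p,
                     normal = matrix(NA_real_, n_units, 3L),
                     glyc = matrix(NA_real_, n_units, 3L))
    ligand <- list(kind = "rna", type = rtype, role = st$role,
                   code = st$code, resid = paste0("R:", seq_len(n_units)),
                   pos = rpos, axis = axis_r, normal = normal, glyc = glyc)
    out[[k]] <- structure(list(id = sprintf("planted_%02d", k),
                               receptor = receptor, ligand = ligand,
                               receptor_kind = "protein",
                               ligand_kind = "rna"),
                          class = "rnp_reduced")
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  attr(out, "planted") <- list(pair = planted_pair, bin = planted_bin,
                               enrichment = enrichment,
                               protein_types = up, rna_types = ur)
  out
}

#' Realised enrichment of the planted cell
#'
#' Recounts contacts on a planted training set and returns the ratio of
#' the planted cell's count to the mean count of the other background
#' type pairs in the same distance bin.
#'
#' @param complexes Output of [make_planted_training_set()].
#' @param scheme An [rnp_scheme()].
#' @return Numeric ratio.
#' @export
realized_enrichment <- function(complexes, scheme = rnp_scheme()) {
  info <- attr(complexes, "planted")
  if (is.null(info)) stop("not a planted training set", call. = FALSE)
  counts <- count_contacts(complexes, scheme)
  slab <- counts$dist[info$protein_types, info$rna_types, info$bin + 1L,
                      drop = TRUE]
  planted <- slab[info$pair[1L], info$pair[2L]]
  slab[info$pair[1L], info$pair[2L]] <- NA
  planted / mean(slab, na.rm = TRUE)
}
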