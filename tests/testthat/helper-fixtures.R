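# Shared fixtures and independent oracles for the test suite.

# Minimal one-residue alanine PDB (5 heavy atoms)
ala_pdb_lines <- function(occupancy = "  1.00") {
  atoms <- list(
    c("N",  0.000, 0.000, 0.000),
    c("CA", 1.458, 0.000, 0.000),
    c("C",  2.009, 1.420, 0.000),
    c("O",  1.251, 2.390, 0.000),
    c("CB", 2.000, -0.800, 1.200))
  vapply(seq_along(atoms), function(k) {
    a <- atoms[[k]]
    sprintf("ATOM  %5d  %-3s ALA A   1    %8.3f%8.3f%8.3f%s  0.00           %s",
            k, a[1], as.numeric(a[2]), as.numeric(a[3]), as.numeric(a[4]),
            occupancy, substr(a[1], 1, 1))
  }, character(1))
}

# Build a bare bead side for synthetic reduced complexes
make_side <- function(kind, types, pos, axis = NULL, normal = NULL,
                      glyc = NULL) {
  n <- length(types)
  pos <- matrix(pos, n, 3, byrow = TRUE)
  if (is.null(axis)) axis <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
  if (is.null(normal)) normal <- matrix(NA_real_, n, 3)
  if (is.null(glyc)) glyc <- matrix(NA_real_, n, 3)
  parts <- strsplit(types, ".", fixed = TRUE)
  list(kind = kind, type = types,
       role = vapply(parts, `[[`, character(1), 2),
       code = vapply(parts, `[[`, character(1), 1),
       resid = paste0(kind, ":", seq_len(n)),
       pos = pos, axis = axis, normal = normal, glyc = glyc)
}

make_reduced <- function(receptor, ligand, id = "synthetic") {
  structure(list(id = id, receptor = receptor, ligand = ligand,
                 receptor_kind = receptor$kind, ligand_kind = ligand$kind),
            class = "rnp_reduced")
}

random_rotation_oracle <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply a rigid motion to every atom of a structure
transform_structure <- function(s, R, t) {
  for (cn in names(s$chains)) {
    for (k in seq_along(s$chains[[cn]]$residues)) {
      xyz <- as.matrix(s$chains[[cn]]$residues[[k]]$atoms[, c("x", "y", "z")])
      new <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
      s$chains[[cn]]$residues[[k]]$atoms$x <- new[, 1]
      s$chains[[cn]]$residues[[k]]$atoms$y <- new[, 2]
      s$chains[[cn]]$residues[[k]]$atoms$z <- new[, 3]
    }
  }
  s
}

# Independent naive implementation of the greedy clustering rule,
# written directly from its verbal description (no shared code).
naive_greedy_cluster <- function(scores, rmsd, top_n, cutoff) {
  sel <- sort(order(scores)[seq_len(min(top_n, length(scores)))])
  pool <- sel
  clusters <- list()
  repeat {
    if (length(pool) == 0) break
    best_row <- NA; best_count <- -1
    for (i in pool) {
      cnt <- sum(rmsd[i, setdiff(pool, i)] < cutoff)
      if (cnt > best_count) { best_count <- cnt; best_row <- i }
    }
    if (best_count < 1) break
    members <- c(best_row,
                 setdiff(pool, best_row)[rmsd[best_row,
                                              setdiff(pool, best_row)] <
                                           cutoff])
    clusters[[length(clusters) + 1]] <- sort(members)
    pool <- setdiff(pool, members)
  }
  if (length(clusters) == 0) return(clusters)
  reps <- vapply(clusters, function(m) m[which.min(scores[m])], numeric(1))
  ord <- order(-lengths(clusters), scores[reps])
  clusters[ord]
}

# Horn's closed-form quaternion superposition: an independent route to
# the optimal rigid fit, used as an oracle against the Kabsch path.
horn_superpose_rmsd <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(mov, 2, cm); B <- sweep(ref, 2, cr)
  S <- t(A) %*% B
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
  fit <- A %*% t(R) + matrix(cr, nrow(A), 3, byrow = TRUE)
  sqrt(mean(rowSums((fit - ref)^2)))
}
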