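mk_res <- function(code, kind, atoms) {
  list(raw_code = code, code = code, chain = "A", seq = "1", icode = " ",
       is_modified = FALSE, kind = kind,
       atoms = data.frame(name = names(atoms),
                          element = substr(names(atoms), 1, 1),
                          x = vapply(atoms, `[[`, numeric(1), 1),
                          y = vapply(atoms, `[[`, numeric(1), 2),
                          z = vapply(atoms, `[[`, numeric(1), 3),
                          hetero = FALSE, stringsAsFactors = FALSE))
}

test_that("glycine reduces to a single CA bead with an N->C axis", {
  r <- mk_res("GLY", "protein",
              list(N = c(-1.2, 0.3, 0), CA = c(0, 0, 0),
                   C = c(1.2, 0.3, 0), O = c(1.6, 1.4, 0)))
  beads <- reduce_protein_residue(r)
  expect_length(beads, 1)
  expect_equal(beads[[1]]$type, "GLY.CA")
  expect_equal(beads[[1]]$position, c(0, 0, 0))
  expect_equal(beads[[1]]$axis,
               (c(1.2, 0.3, 0) - c(-1.2, 0.3, 0)) / 2.4)
})

test_that("alanine SC1 sits on CB and sets the CA axis", {
  r <- mk_res("ALA", "protein",
              list(N = c(-1, 0, 0), CA = c(0, 0, 0), C = c(1, 0.5, 0),
                   O = c(1, 1.7, 0), CB = c(1, 0, 0)))
  beads <- reduce_protein_residue(r)
  expect_length(beads, 2)
  expect_equal(beads[[2]]$type, "ALA.SC1")
  expect_equal(beads[[2]]$position, c(1, 0, 0))
  expect_equal(beads[[1]]$axis, c(1, 0, 0))  # CA -> SC1
})

test_that("lysine beads are the hand-computed layer centroids", {
  atoms <- list(N = c(-1, 0, 0), CA = c(0, 0, 0), C = c(1, 0.4, 0),
                O = c(1, 1.6, 0),
                CB = c(1.0, -1.0, 0.2), CG = c(2.0, -1.6, 0.4),
                CD = c(3.0, -2.4, 0.6), CE = c(4.0, -3.0, 0.8),
                NZ = c(5.0, -3.8, 1.0))
  beads <- reduce_protein_residue(mk_res("LYS", "protein", atoms))
  expect_length(beads, 3)
  expect_equal(beads[[2]]$position, (atoms$CB + atoms$CG) / 2)
  expect_equal(beads[[3]]$position, (atoms$CD + atoms$CE + atoms$NZ) / 3)
  expect_equal(vapply(beads, `[[`, character(1), "type"),
               c("LYS.CA", "LYS.SC1", "LYS.SC2"))
})

test_that("missing CA skips the residue and partial side chains warn", {
  no_ca <- mk_res("ALA", "protein", list(N = c(0, 0, 0), C = c(1, 0, 0)))
  expect_warning(beads <- reduce_protein_residue(no_ca), "CA")
  expect_length(beads, 0)
  partial <- mk_res("LYS", "protein",
                    list(N = c(-1, 0, 0), CA = c(0, 0, 0), C = c(1, 0, 0),
                         CB = c(1, -1, 0), CG = c(2, -1.5, 0),
                         CD = c(3, -2, 0)))  # CE, NZ absent
  expect_warning(beads <- reduce_protein_residue(partial), "1/3 atoms")
  expect_length(beads, 3)
  expect_equal(beads[[3]]$position, c(3, -2, 0))
})

test_that("pyrimidines get P+RIB+PYR with an exact planar edge frame", {
  hex <- function(deg) 1.4 * c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  ring <- list(N1 = hex(180), C2 = hex(240), N3 = hex(300),
               C4 = hex(0), C5 = hex(60), C6 = hex(120))
  atoms <- c(list(P = c(-6, 0, 1), OP1 = c(-6.8, -0.8, 1.2),
                  OP2 = c(-6.8, 0.8, 1.2),
                  "C1'" = c(-2.88, 0, 0), "C2'" = c(-3.3, 1.2, 0.3),
                  "C3'" = c(-4.5, 0.9, 0.5), "C4'" = c(-4.6, -0.6, 0.4),
                  "O4'" = c(-3.4, -1.2, 0.2)), ring)
  beads <- reduce_rna_residue(mk_res("U", "rna", atoms))
  roles <- vapply(beads, `[[`, character(1), "role")
  expect_equal(roles, c("P", "RIB", "PYR"))
  pyr <- beads[[3]]
  expect_equal(pyr$position, c(0, 0, 0), tolerance = 1e-12)  # hexagon centre
  expect_equal(abs(pyr$normal[3]), 1, tolerance = 1e-9)
  # glycosidic direction: C1' -> N1, in plane
  expect_equal(pyr$glyc, c(1.48, 0, 0) / 1.48, tolerance = 1e-9)
  expect_equal(sum(pyr$normal * pyr$glyc), 0, tolerance = 1e-9)
  # P bead = phosphate-group centroid
  expect_equal(beads[[1]]$position,
               (atoms$P + atoms$OP1 + atoms$OP2) / 3)
})

test_that("purines get two ring beads; 5'-terminal residues lack P", {
  s <- make_toy_complex(3, 2, seed = 2, rna_sequence = c("G", "A"))
  g_res <- s$chains$B$residues[[1]]
  g_res$atoms <- g_res$atoms[g_res$atoms$name != "P", ]  # strip phosphate
  expect_warning(beads <- reduce_rna_residue(g_res), "phosphate")
  expect_equal(vapply(beads, `[[`, character(1), "role"),
               c("RIB", "PUR5", "PUR6"))
  # PUR6 centroid equals the mean of the six-ring atoms
  six <- g_res$atoms[g_res$atoms$name %in%
                       c("N1", "C2", "N3", "C4", "C5", "C6"), ]
  expect_equal(beads[[3]]$position,
               unname(colMeans(as.matrix(six[, c("x", "y", "z")]))),
               tolerance = 1e-9)
})

test_that("residues with neither ribose nor ring atoms are rejected", {
  bad <- mk_res("U", "rna", list(P = c(0, 0, 0), OP1 = c(1, 0, 0)))
  expect_error(reduce_rna_residue(bad), "rejected")
})

test_that("bead census matches the declared type enumeration", {
  tp <- rnp_bead_types()
  expect_length(tp$protein, 52)
  expect_length(tp$rna, 14)
  s <- make_toy_complex(20, 4, seed = 3,
                        protein_sequence = names(rnpscore:::.protein_bead_atoms),
                        rna_sequence = c("A", "C", "G", "U"))
  rc <- reduce_complex(s, "A", "B")
  # per-residue bead counts from the membership table, plus CA
  expected_protein <- sum(lengths(rnpscore:::.protein_bead_atoms) + 1L)
  expect_equal(nrow(rc$receptor$pos), expected_protein)
  expect_equal(nrow(rc$ligand$pos), 14)  # 4+3+4+3 with phosphates present
  expect_setequal(unique(rc$receptor$type),
                  tp$protein[tp$protein %in% rc$receptor$type])
})

test_that("reduce_complex is additive, swappable and validates chains", {
  s <- make_toy_complex(3, 2, seed = 5)
  rc <- reduce_complex(s, "A", "B")
  per_res <- c(
    vapply(s$chains$A$residues,
           function(r) length(reduce_protein_residue(r)), integer(1)),
    vapply(s$chains$B$residues,
           function(r) length(reduce_rna_residue(r)), integer(1)))
  expect_equal(nrow(rc$receptor$pos) + nrow(rc$ligand$pos), sum(per_res))
  swapped <- reduce_complex(s, receptor_chains = "B", ligand_chains = "A")
  expect_equal(swapped$receptor, rc$ligand)
  expect_equal(swapped$ligand, rc$receptor)
  expect_error(reduce_complex(s, "A", "Z"), "Z")
  expect_error(reduce_complex(s, "A", "A"), "both")
})

test_that("reduction is equivariant under rigid motions", {
  s <- make_toy_complex(4, 3, seed = 9)
  rc <- reduce_complex(s, "A", "B")
  set.seed(31)
  for (i in 1:5) {
    R <- random_rotation_oracle()
    t_vec <- rnorm(3, sd = 20)
    rc2 <- reduce_complex(transform_structure(s, R, t_vec), "A", "B")
    rc_moved <- transform_complex(rc, R, t_vec)
    expect_equal(rc2$receptor$pos, rc_moved$receptor$pos, tolerance = 1e-9)
    expect_equal(rc2$ligand$pos, rc_moved$ligand$pos, tolerance = 1e-9)
    expect_equal(rc2$ligand$axis, rc_moved$ligand$axis, tolerance = 1e-9)
    expect_equal(rc2$ligand$normal, rc_moved$ligand$normal,
                 tolerance = 1e-9)
  }
})
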