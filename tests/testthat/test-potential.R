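# a complex with exactly one contact at a known geometry:
# ALA.CA at 4.2 A from A.PUR6, 30 deg off the base normal, on the WC side
one_contact_complex <- function() {
  d <- 4.2; th <- 30 * pi / 180
  # direction in the (glyc, normal) half-space rotated 180 deg in-plane:
  # in-plane component opposite the glycosidic direction -> phi = 180
  dir <- c(-sin(th), 0, cos(th))
  rna <- make_side("rna", "A.PUR6", c(0, 0, 0),
                   axis = matrix(c(0, 0, 1), 1),
                   normal = matrix(c(0, 0, 1), 1),
                   glyc = matrix(c(1, 0, 0), 1))
  prot <- make_side("protein", "ALA.CA", d * dir)
  make_reduced(prot, rna, id = "one_contact")
}

test_that("count_contacts bins a known single contact into the right cells", {
  counts <- suppressWarnings(count_contacts(list(cx = one_contact_complex())))
  expect_equal(sum(counts$dist), 1)
  expect_equal(counts$dist["ALA.CA", "A.PUR6", "d4"], 1)   # 4.2 -> bin 4
  expect_equal(counts$angle["ALA.CA", "A.PUR6", "a1"], 1)  # 30 -> bin 1
  expect_equal(counts$edge["ALA.CA", "A.PUR6", "WC"], 1)
  expect_equal(sum(counts$edge), 1)
})

test_that("counts are additive and empty interfaces count as zero", {
  s <- make_toy_complex(5, 3, seed = 6)
  rc <- reduce_complex(s, "A", "B")
  c1 <- count_contacts(list(a = rc))
  c2 <- count_contacts(list(a = rc, b = rc))
  expect_equal(c2$dist, 2 * c1$dist)
  expect_equal(c2$angle, 2 * c1$angle)
  expect_equal(c2$edge, 2 * c1$edge)
  far <- transform_complex(rc, diag(3), c(100, 0, 0), side = "ligand")
  expect_warning(c0 <- count_contacts(list(far = far)), "no protein-RNA")
  expect_equal(sum(c0$dist), 0)
  # every contact feeds each term's table once
  expect_equal(sum(c1$dist), sum(c1$angle))
})

test_that("mole fractions are bead-count ratios summing to one", {
  prot <- make_side("protein",
                    c(rep("ALA.CA", 3), rep("GLY.CA", 7)),
                    as.vector(t(matrix(seq(0, 270, 30), 10, 3))))
  rna <- make_side("rna", c("A.P", "U.P"),
                   as.vector(t(matrix(c(0, 0, 500, 30, 0, 500), 2,
                                      byrow = TRUE))))
  X <- suppressWarnings(mole_fractions(list(make_reduced(prot, rna))))
  expect_equal(unname(X$protein["ALA.CA"]), 0.3)
  expect_equal(unname(X$protein["GLY.CA"]), 0.7)
  expect_equal(unname(X$rna[c("A.P", "U.P")]), c(0.5, 0.5))
  expect_equal(sum(X$protein), 1, tolerance = 1e-12)
  expect_equal(sum(X$rna), 1, tolerance = 1e-12)
})

test_that("the quasi-chemical reference conserves per-bin totals", {
  set.seed(23)
  complexes <- lapply(1:3, function(s) {
    reduce_complex(make_toy_complex(6, 4, seed = s), "A", "B")
  })
  counts <- count_contacts(complexes)
  ref <- quasi_expected(counts)
  for (term in c("dist", "angle", "edge")) {
    obs_tot <- apply(counts[[term]], 3, sum)
    exp_tot <- apply(ref[[term]], 3, sum)
    expect_equal(exp_tot, obs_tot, tolerance = 1e-9)
  }
  # single-type limit: X_i = X_j = 1 reproduces the bin totals
  X1 <- list(protein = c("ALA.CA" = 1) ,rna = c("A.P" = 1))
  tp <- rnp_bead_types()
  X_full <- list(
    protein = stats::setNames(as.numeric(tp$protein == "ALA.CA"),
                              tp$protein),
    rna = stats::setNames(as.numeric(tp$rna == "A.P"), tp$rna))
  ref1 <- quasi_expected(counts, X_full)
  expect_equal(ref1$dist["ALA.CA", "A.P", ],
               apply(counts$dist, 3, sum))
})

test_that("the DARS reference scales decoy counts to native totals", {
  s <- make_toy_complex(6, 4, seed = 14)
  rc <- reduce_complex(s, "A", "B")
  native <- count_contacts(list(rc))
  # decoys identical to natives: reference equals observation
  same <- dars_expected(native, native)
  expect_equal(same$dist, native$dist)
  # duplicated decoy set: scale 1/2 restores the native totals
  twice <- count_contacts(list(rc, rc))
  half <- dars_expected(twice, native)
  expect_equal(half$dist, native$dist)
  expect_equal(sum(half$angle), sum(native$angle))
  empty <- suppressWarnings(count_contacts(list(
    transform_complex(rc, diag(3), c(500, 0, 0), side = "ligand"))))
  expect_error(dars_expected(empty, native), "larger decoy sets")
})

test_that("energy_table implements reverse Boltzmann inversion exactly", {
  s <- make_toy_complex(6, 4, seed = 14)
  counts <- count_contacts(list(reduce_complex(s, "A", "B")))
  ref <- quasi_expected(counts)
  # N_obs = N_exp -> zero energies, any pseudocount
  same <- dars_expected(counts, counts)
  tab0 <- energy_table(counts, same, pseudocount = 1)
  expect_true(all(tab0$energies$dist == 0))
  # forced value: obs 2, exp 1, alpha 0 -> -ln 2
  c2 <- counts; c2$dist[] <- 2
  r1 <- same; r1$dist[] <- 1; r1$angle[] <- 1; r1$edge[] <- 1
  c2$angle[] <- 1; c2$edge[] <- 1
  tab <- energy_table(c2, r1, RT = 1, pseudocount = 0)
  expect_equal(tab$energies$dist[1, 1, 1], -log(2), tolerance = 1e-12)
  expect_error(energy_table(counts, ref, pseudocount = 0),
               "strictly positive")
  # scalar re-computation oracle on random tables
  set.seed(99)
  co <- counts; re <- same
  co$dist[] <- rpois(length(co$dist), 3)
  re$dist[] <- runif(length(re$dist), 0, 6)
  tab2 <- energy_table(co, re, RT = 0.7, pseudocount = 1)
  idx <- cbind(sample(52, 50, TRUE), sample(14, 50, TRUE),
               sample(9, 50, TRUE))
  for (k in 1:50) {
    o <- co$dist[idx[k, , drop = FALSE]]
    e <- re$dist[idx[k, , drop = FALSE]]
    expect_equal(tab2$energies$dist[idx[k, , drop = FALSE]],
                 -0.7 * log((o + 1) / (e + 1)), tolerance = 1e-12)
  }
})

test_that("energies decrease strictly as a cell's observations grow", {
  s <- make_toy_complex(6, 4, seed = 14)
  counts <- count_contacts(list(reduce_complex(s, "A", "B")))
  ref <- quasi_expected(counts)
  tab1 <- energy_table(counts, ref)
  bumped <- counts
  bumped$dist["ALA.CA", "A.P", "d5"] <-
    bumped$dist["ALA.CA", "A.P", "d5"] + 5
  tab2 <- energy_table(bumped, ref)
  expect_lt(tab2$energies$dist["ALA.CA", "A.P", "d5"],
            tab1$energies$dist["ALA.CA", "A.P", "d5"])
})

test_that("leave-one-out tables drop exactly the held-out complex", {
  complexes <- lapply(1:2, function(s) {
    reduce_complex(make_toy_complex(6, 4, seed = s), "A", "B")
  })
  names(complexes) <- c("c1", "c2")
  fit <- rnp_potential(complexes, reference = "quasi")
  loo <- loo_tables(fit)
  solo2 <- rnp_potential(complexes["c2"], reference = "quasi")
  expect_equal(loo$c1$energies, solo2$table$energies)
  # conservation: LOO counts + held-out counts = full counts
  cm <- rnpscore:::.counts_without(fit$counts, "c1")
  expect_equal(cm$dist + fit$counts$per_complex$c1$dist, fit$counts$dist)
  expect_error(loo_tables(rnp_potential(complexes[1], reference = "quasi")),
               "at least two")

  five <- lapply(1:5, function(s) {
    reduce_complex(make_toy_complex(6, 4, seed = s + 40), "A", "B")
  })
  names(five) <- paste0("x", 1:5)
  fit5 <- rnp_potential(five, reference = "quasi", loo = TRUE)
  for (id in names(five)) {
    expect_gt(sum(fit5$loo[[id]]$energies$dist !=
                    fit5$table$energies$dist), 0)
  }
})

test_that("scoring sums the four terms with the declared clash rule", {
  cx <- one_contact_complex()
  counts <- suppressWarnings(count_contacts(list(cx)))
  ref <- quasi_expected(counts)
  tab <- energy_table(counts, ref)
  s <- score_complex(cx, tab)
  ed <- tab$energies$dist["ALA.CA", "A.PUR6", "d4"]
  ea <- tab$energies$angle["ALA.CA", "A.PUR6", "a1"]
  es <- tab$energies$edge["ALA.CA", "A.PUR6", "WC"]
  expect_equal(s$Ed, ed)
  expect_equal(s$Ea, ea)
  expect_equal(s$Es, es)
  expect_equal(s$Ep, 0)
  expect_identical(s$E, s$Ed + s$Ea + s$Es + s$Ep)

  # zero-contact complex scores exactly zero
  far <- transform_complex(cx, diag(3), c(100, 0, 0), side = "ligand")
  s0 <- score_complex(far, tab)
  expect_equal(s0$E, 0)
  expect_equal(s0$n_contacts, 0L)

  # a 2.5 A pair is one clash worth +1 by default
  close <- cx
  close$receptor$pos[1, ] <- c(2.5, 0, 0)
  sc <- score_complex(close, tab)
  expect_equal(sc$n_clashes, 1L)
  expect_equal(sc$Ep, 1)

  # unknown bead type is named in the error
  bad <- cx
  bad$receptor$type[1] <- "ZZZ.CA"
  expect_error(score_complex(bad, tab), "ZZZ.CA")
})

test_that("scores are invariant under rigid motions of the whole complex", {
  complexes <- lapply(1:3, function(s) {
    reduce_complex(make_toy_complex(8, 5, seed = s), "A", "B")
  })
  fit <- rnp_potential(complexes, reference = "quasi")
  base <- score_complex(complexes[[1]], fit$table)
  set.seed(55)
  for (i in 1:20) {
    moved <- transform_complex(complexes[[1]], random_rotation_oracle(),
                               rnorm(3, sd = 50))
    s <- score_complex(moved, fit$table)
    expect_equal(s$E, base$E, tolerance = 1e-9)
    expect_identical(s$n_contacts, base$n_contacts)
  }
})

test_that("potential tables serialize and round-trip bit-exactly", {
  complexes <- lapply(1:3, function(s) {
    reduce_complex(make_toy_complex(6, 4, seed = s), "A", "B")
  })
  fit <- rnp_potential(complexes, reference = "quasi", RT = 0.59,
                       pseudocount = 0.5)
  path <- tempfile(fileext = ".tsv")
  write_potential(fit, path)
  back <- read_potential(path)
  expect_identical(back$table$energies, fit$table$energies)
  expect_identical(back$counts$dist, fit$counts$dist)
  expect_identical(back$table$RT, fit$table$RT)
  expect_equal(back$reference_kind, "quasi")
  sc1 <- score_complex(complexes[[1]], fit$table)
  sc2 <- score_complex(complexes[[1]], back$table)
  expect_identical(sc1$E, sc2$E)
})

test_that("the fitted model exposes the standard S3 surface", {
  complexes <- lapply(1:3, function(s) {
    reduce_complex(make_toy_complex(6, 4, seed = s), "A", "B")
  })
  names(complexes) <- paste0("c", 1:3)
  fit <- rnp_potential(complexes, reference = "quasi")
  expect_output(print(fit), "QUASI")
  expect_output(print(summary(fit)), "most favourable")
  cf <- coef(fit)
  expect_equal(nrow(cf), 52 * 14 * 9 * 2 + 52 * 14 * 3)
  expect_true(all(c("term", "energy", "n_obs", "n_exp") %in% names(cf)))
  pr <- predict(fit, complexes)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$E, pr$Ed + pr$Ea + pr$Es + pr$Ep)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
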