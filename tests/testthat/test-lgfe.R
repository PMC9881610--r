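make_score_fixture <- function(seed = 1) {
  set.seed(seed)
  types <- c("GENN", "GEND", "MAMN")
  grids <- lapply(types, function(tn)
    fragmap_grid(array(runif(125, -5, 3), c(5, 5, 5)), origin = c(-2, -2, -2),
                 spacing = 1, map_type = tn))
  maps <- fragmap_set(grids)
  n <- 10
  xyz <- matrix(runif(n * 3, -3, 3), n, 3)
  labels <- sample(c(types, "UNCLASSIFIED"), n, replace = TRUE)
  lig <- ligand("probe",
                atoms = data.frame(element = "C", charge = 0L, aromatic = FALSE,
                                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                bonds = data.frame(i = seq_len(n - 1), j = 2:n, order = 1L))
  assignment <- structure(labels, names = seq_len(n),
                          class = "atom_class_assignment")
  list(maps = maps, lig = lig, xyz = xyz, assignment = assignment,
       types = types)
}

test_that("LGFE is the exact sum of per-atom voxel lookups", {
  fx <- make_score_fixture()
  w <- weight_vector(fx$types, c(0.7, 1.3, 0.2))
  bd <- atomic_gfes(conformer(fx$lig), fx$assignment, fx$maps, w)
  expect_equal(bd$total, sum(bd$per_atom))
  expect_equal(bd$total,
               oracle_lgfe(fx$xyz, fx$assignment, fx$maps, w),
               tolerance = 1e-12)
  expect_equal(lgfe(conformer(fx$lig), fx$assignment, fx$maps, w), bd$total)
  # unclassified atoms contribute exactly zero
  expect_true(all(bd$per_atom[fx$assignment == "UNCLASSIFIED"] == 0))
})

test_that("scoring is linear in the weights and zero at zero weight", {
  fx <- make_score_fixture(2)
  w0 <- weight_vector(fx$types, 0)
  bd0 <- atomic_gfes(conformer(fx$lig), fx$assignment, fx$maps, w0)
  expect_true(all(bd0$per_atom == 0))
  expect_equal(bd0$total, 0)
  w1 <- weight_vector(fx$types, c(1, 0.5, 2))
  for (alpha in c(0.25, 0.5, 2)) {
    wa <- weight_vector(fx$types, alpha * unclass(w1))
    expect_equal(lgfe(conformer(fx$lig), fx$assignment, fx$maps, wa),
                 alpha * lgfe(conformer(fx$lig), fx$assignment, fx$maps, w1),
                 tolerance = 1e-12)
  }
})

test_that("LGFE is invariant to atom order and missing maps warn", {
  fx <- make_score_fixture(3)
  base <- lgfe(conformer(fx$lig), fx$assignment, fx$maps)
  perm <- sample(nrow(fx$xyz))
  lig_p <- fx$lig
  lig_p$atoms <- fx$lig$atoms[perm, ]
  rownames(lig_p$atoms) <- NULL
  inv <- order(perm)
  lig_p$bonds$i <- inv[fx$lig$bonds$i]
  lig_p$bonds$j <- inv[fx$lig$bonds$j]
  asg_p <- structure(as.character(fx$assignment)[perm],
                     names = seq_along(perm), class = "atom_class_assignment")
  expect_equal(lgfe(conformer(lig_p), asg_p, fx$maps), base, tolerance = 1e-12)
  # a label with no grid contributes zero, with a warning
  asg_m <- fx$assignment
  asg_m[1] <- "ACEO"
  expect_warning(bd <- atomic_gfes(conformer(fx$lig), asg_m, fx$maps),
                 "no FragMap")
  expect_equal(bd$per_atom[1], 0)
})

test_that("moiety group sums over a partition reproduce the total exactly", {
  fx <- make_score_fixture(4)
  bd <- atomic_gfes(conformer(fx$lig), fx$assignment, fx$maps)
  groups <- split(seq_len(10), rep(1:3, length.out = 10))
  sums <- group_gfe_sums(bd, groups)
  expect_equal(sum(sums), bd$total, tolerance = 1e-14)
})

test_that("Henderson-Hasselbalch fractions and mixing follow the closed form", {
  # at pKa = pH the two states mix 50/50
  expect_equal(hh_weighted_lgfe(-6, -8, pKa = 7.4, pH = 7.4, kind = "base"), -7)
  # base two units above the pH is almost fully charged
  expect_equal(charged_fraction(9.4, 7.4, "base"), 1 / (1 + 1e-2))
  expect_equal(charged_fraction(9.4, 7.4, "base"), 0.990099, tolerance = 1e-6)
  # acids mirror bases
  expect_equal(charged_fraction(5.4, 7.4, "acid"), 1 / (1 + 1e-2))
  # extreme pKa limits recover the pure states
  expect_equal(hh_weighted_lgfe(-6, -8, pKa = -1000, pH = 7.4, "base"), -6)
  expect_equal(hh_weighted_lgfe(-6, -8, pKa = 1000, pH = 7.4, "base"), -8)
  expect_error(hh_weighted_lgfe(-6, -8, 7, kind = "zwitter"))
  expect_error(hh_weighted_lgfe(NaN, -8, 7, kind = "base"), "finite")
})

test_that("HH weighting is a convex combination of the state scores", {
  set.seed(5)
  for (k in 1:50) {
    ln <- runif(1, -12, 0); lc <- runif(1, -12, 0)
    v <- hh_weighted_lgfe(ln, lc, pKa = runif(1, 2, 12), pH = 7.4,
                          kind = sample(c("acid", "base"), 1))
    expect_gte(v, min(ln, lc) - 1e-12)
    expect_lte(v, max(ln, lc) + 1e-12)
  }
})

test_that("LGFE to pIC50 conversion uses the thermodynamic constant at 300 K", {
  expect_equal(lgfe_to_pic50(0), 0)
  expect_equal(lgfe_to_pic50(-8.2), 8.2 / (log(10) * 0.0019872 * 300),
               tolerance = 1e-12)
  expect_equal(lgfe_to_pic50(-8.2), 8.2 / 1.3728, tolerance = 1e-3)
  expect_equal(lgfe_to_pic50(-5, mode = "affine", a = 1, b = 0), 5)
  expect_equal(lgfe_to_pic50(-5, mode = "affine", a = 0.5, b = 2), 4.5)
})
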