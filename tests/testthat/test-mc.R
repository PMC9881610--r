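test_that("Metropolis accepts downhill always and uphill never at 0 K", {
  set.seed(1)
  expect_true(all(metropolis(rep(-1, 100), 300)))
  expect_true(all(metropolis(rep(0, 100), 300)))
  expect_false(any(metropolis(rep(1, 100), 0)))
  expect_error(metropolis(1, -10), ">= 0")
})

test_that("random placement stays in the sphere with unchanged geometry", {
  lig <- n_butane()
  proto <- dock_protocol(pocket_center = c(2, -1, 3), placement_radius = 10)
  d0 <- dist(coords(lig))
  set.seed(3)
  cents <- matrix(0, 500, 3)
  for (k in 1:500) {
    conf <- random_placement(lig, proto)
    cents[k, ] <- colMeans(conf$xyz)
    expect_equal(as.vector(dist(conf$xyz)), as.vector(d0), tolerance = 1e-9)
  }
  r <- sqrt(rowSums(sweep(cents, 2, proto$pocket_center)^2))
  expect_true(all(r <= 10 + 1e-9))
  # mean centroid near the center (CLT bound: sd of uniform-ball coord
  # is R*sqrt(1/5); 4 sigma of the mean over 500 draws)
  expect_true(all(abs(colMeans(cents) - proto$pocket_center) <
                    4 * 10 * sqrt(1 / 5) / sqrt(500)))
  # determinism under a fixed seed
  set.seed(99); a <- random_placement(lig, proto)
  set.seed(99); b <- random_placement(lig, proto)
  expect_identical(a$xyz, b$xyz)
})

test_that("rigid-body moves preserve all interatomic distances", {
  lig <- benzene()  # no rotatable bonds: only translate/rotate proposed
  conf <- conformer(lig)
  d0 <- as.vector(dist(conf$xyz))
  set.seed(4)
  for (k in 1:100) {
    conf2 <- propose_move(conf, torsions = list())
    expect_equal(as.vector(dist(conf2$xyz)), d0, tolerance = 1e-9)
  }
})

test_that("torsion rotation round-trips and moves only one side", {
  lig <- n_butane()
  tors <- rotatable_bonds(lig)
  xyz <- coords(lig)
  theta <- 0.7
  rot_about <- function(xyz, tor, ang) {
    axis <- xyz[tor$k, ] - xyz[tor$j, ]
    R <- gfedock:::.rotation_matrix(axis, ang)
    piv <- xyz[tor$j, ]
    m <- tor$movable
    xyz[m, ] <- sweep(sweep(xyz[m, , drop = FALSE], 2, piv) %*% t(R), 2,
                      piv, "+")
    xyz
  }
  fwd <- rot_about(xyz, tors[[1]], theta)
  static <- setdiff(seq_len(4), tors[[1]]$movable)
  expect_equal(fwd[static, ], xyz[static, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fwd, xyz)))
  back <- rot_about(fwd, tors[[1]], -theta)
  expect_equal(back, xyz, tolerance = 1e-9)
  # bond lengths are preserved by the torsion
  blen <- function(m) sqrt(rowSums((m[lig$bonds$i, ] - m[lig$bonds$j, ])^2))
  expect_equal(blen(fwd), blen(xyz), tolerance = 1e-9)
})

test_that("a zero-step run returns its placement pose; best is monotone", {
  maps <- flat_maps(-1)
  lig <- make_probe <- ligand("p", data.frame(element = "C", charge = 0L,
                                              aromatic = FALSE, x = 0, y = 0,
                                              z = 0),
                              data.frame(i = integer(0), j = integer(0),
                                         order = integer(0)))
  proto <- dock_protocol(placement_radius = 2, n_min_steps = 0, n_mc_steps = 0,
                         n_anneal_steps = 0)
  set.seed(5)
  r <- anneal_run(lig, maps, protocol = proto)
  set.seed(5)
  placed <- random_placement(lig, proto)
  expect_identical(r$conformer$xyz, placed$xyz)
  # with steps, the returned energy never exceeds the placement energy
  spec <- synthetic_spec(map_types = "GENN")
  wmaps <- make_fragmaps(spec)
  proto2 <- dock_protocol(n_min_steps = 20, n_mc_steps = 100,
                          n_anneal_steps = 200)
  for (s in 1:5) {
    set.seed(s)
    init <- random_placement(lig, proto2)
    e_init <- lgfe(init, classify_atoms(lig), wmaps)
    set.seed(s)
    r <- anneal_run(lig, wmaps, protocol = proto2)
    expect_lte(r$lgfe, e_init + 1e-12)
  }
})

test_that("docking on a flat map gives the closed-form score and converges", {
  val <- -0.8
  maps <- flat_maps(val, types = c("GENN", "GEND"))
  lig <- methanol()  # 1 C (GENN), 1 O (GEND), 4 H (unclassified)
  proto <- dock_protocol(placement_radius = 2, n_min_steps = 5, n_mc_steps = 20,
                         n_anneal_steps = 20, n_independent = 2,
                         runs_per_block = 1, rng_seed = 1)
  w <- weight_vector(c("GENN", "GEND"), c(1, 0.5))
  res <- dock(lig, maps, proto, w)
  expect_equal(res$best_lgfe, val * 1 + 0.5 * val * 1, tolerance = 1e-12)
  expect_true(res$converged)
  expect_equal(res$runs_executed, 2L)
})

test_that("a degenerate one-run protocol executes once and cannot converge", {
  maps <- flat_maps(-1)
  lig <- benzene()
  proto <- dock_protocol(placement_radius = 3, n_min_steps = 0, n_mc_steps = 10,
                         n_anneal_steps = 0, n_independent = 1,
                         runs_per_block = 1)
  res <- dock(lig, maps, proto)
  expect_equal(res$runs_executed, 1L)
  expect_false(res$converged)
})

test_that("dock results are self-consistent and seed-deterministic", {
  spec <- synthetic_spec(map_types = c("GENN", "GEND"))
  maps <- make_fragmaps(spec)
  lig <- methanol()
  proto <- dock_protocol(n_min_steps = 20, n_mc_steps = 200,
                         n_anneal_steps = 400, n_independent = 2,
                         runs_per_block = 2, rng_seed = 17)
  r1 <- dock(lig, maps, proto)
  r2 <- dock(lig, maps, proto)
  expect_identical(r1$best_conformer$xyz, r2$best_conformer$xyz)
  expect_identical(r1$best_lgfe, r2$best_lgfe)
  expect_identical(r1$run_lgfes, r2$run_lgfes)
  # reported score equals a fresh re-evaluation of the pose
  expect_equal(r1$best_lgfe,
               lgfe(r1$best_conformer, classify_atoms(lig), maps),
               tolerance = 1e-12)
  expect_lte(r1$runs_executed, proto$max_runs)
  # best-seen LGFE is the minimum of the per-run scores
  expect_equal(r1$best_lgfe, min(r1$run_lgfes))
})

test_that("ionization pairs dock both states", {
  spec <- synthetic_spec(map_types = c("GENN", "MAMN"))
  maps <- make_fragmaps(spec)
  charged <- methylammonium()
  neutral <- charged
  neutral$atoms$charge <- 0L
  pair <- ionization_pair(neutral, charged, pKa = 10.6, kind = "base")
  proto <- dock_protocol(n_min_steps = 10, n_mc_steps = 50,
                         n_anneal_steps = 100, n_independent = 1,
                         runs_per_block = 2)
  res <- suppressWarnings(dock(pair, maps, proto))
  expect_named(res, c("neutral", "charged"))
  expect_s3_class(res$neutral, "dock_result")
  # the charged state sees the MAMN map through its N+; the neutral N
  # (a donor with no GEND map here) warns and contributes nothing
  expect_true(is.finite(res$charged$best_lgfe))
})
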