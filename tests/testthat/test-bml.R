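test_that("flat-bottom penalty matches its closed form", {
  cfg <- bml_config()
  expect_equal(flat_bottom_penalty(c(0.05, 1, 2), cfg), 0)
  expect_equal(flat_bottom_penalty(2.5, cfg), 5000 * 0.5^2)
  expect_equal(flat_bottom_penalty(0.04, cfg), 5000 * 0.01^2)
  expect_equal(flat_bottom_penalty(c(2.5, 0.04), cfg), 1250 + 0.5)
})

test_that("the objective equals an independent -R + penalty computation", {
  set.seed(1)
  spec <- synthetic_spec(n_ligands = 20, rng_seed = 3)
  d <- make_bml_dataset(spec)
  cfg <- bml_config()
  for (k in 1:20) {
    w <- runif(5, 0, 2.5)
    pred <- as.vector(d$table$G %*% w) / (-log(10) * 0.0019872 * 300)
    manual <- -cor(pred, d$table$exp_pic50) +
      5000 * sum(pmax(0, w - 2)^2 + pmax(0, 0.05 - w)^2)
    expect_equal(bml_objective(w, d$table, cfg), manual, tolerance = 1e-12)
  }
})

test_that("degenerate weight vectors trigger the zero-variance guard", {
  spec <- synthetic_spec(n_ligands = 10, rng_seed = 4)
  d <- make_bml_dataset(spec)
  cfg <- bml_config()
  expect_warning(loss <- bml_objective(rep(0, 5), d$table, cfg),
                 "zero-variance")
  expect_equal(loss, 0 + flat_bottom_penalty(rep(0, 5), cfg))
})

test_that("a zero-step chain returns unit weights", {
  spec <- synthetic_spec(n_ligands = 10, rng_seed = 5)
  d <- make_bml_dataset(spec)
  w <- mcsa_optimize(d$table, bml_config(n_steps = 0))
  expect_equal(as.numeric(w), rep(1, 5))
})

test_that("MCSA recovers near-perfect correlation on noiseless data", {
  spec <- synthetic_spec(n_ligands = 30, noise_sigma = 0, rng_seed = 6)
  d <- make_bml_dataset(spec)
  # the true weights score R = 1 by construction
  expect_equal(cor(lgfe_to_pic50(as.vector(d$table$G %*% d$true_weights)),
                   d$table$exp_pic50), 1, tolerance = 1e-12)
  w <- mcsa_optimize(d$table, bml_config(rng_seed = 7))
  expect_gte(attr(w, "metric"), 0.999)
})

test_that("the reported loss matches re-evaluating the returned weights", {
  spec <- synthetic_spec(n_ligands = 25, rng_seed = 8)
  d <- make_bml_dataset(spec)
  cfg <- bml_config(n_steps = 5000, rng_seed = 9)
  w <- mcsa_optimize(d$table, cfg)
  expect_equal(bml_objective(unclass(w), d$table, cfg), attr(w, "loss"),
               tolerance = 1e-12)
})

test_that("rescaling the table and inversely rescaling weights leaves predictions unchanged", {
  spec <- synthetic_spec(n_ligands = 15, rng_seed = 10)
  d <- make_bml_dataset(spec)
  w <- runif(5, 0.1, 2)
  t2 <- gfe_table(2 * d$table$G, d$table$exp_pic50)
  expect_equal(as.vector(t2$G %*% (w / 2)), as.vector(d$table$G %*% w),
               tolerance = 1e-12)
})

test_that("the table builder reproduces lgfe() on the source poses", {
  spec <- synthetic_spec(n_ligands = 4, size_range = c(3, 5), rng_seed = 11)
  maps <- make_fragmaps(spec)
  ls_ <- make_ligand_set(spec)
  proto <- dock_protocol(n_min_steps = 10, n_mc_steps = 50,
                         n_anneal_steps = 100, n_independent = 1,
                         runs_per_block = 1)
  results <- lapply(seq_along(ls_$ligands), function(k) {
    proto$rng_seed <- k
    dock(ls_$ligands[[k]], maps, proto)
  })
  tab <- build_gfe_table(results, maps, exp_pic50 = rnorm(4))
  for (k in 1:4) {
    # unit-weight row sum equals the docked score
    expect_equal(sum(tab$G[k, ]), results[[k]]$best_lgfe, tolerance = 1e-10)
    # arbitrary weights: table prediction equals a fresh weighted rescore
    w <- weight_vector(names(maps), runif(5, 0.1, 2))
    expect_equal(as.vector(tab$G[k, , drop = FALSE] %*% unclass(w)),
                 lgfe(results[[k]]$best_conformer,
                      classify_atoms(ls_$ligands[[k]]), maps, w),
                 tolerance = 1e-10)
  }
})

test_that("redocking with unit weights reproduces the baseline metrics", {
  spec <- synthetic_spec(n_ligands = 5, size_range = c(3, 4), rng_seed = 12)
  maps <- make_fragmaps(spec)
  ls_ <- make_ligand_set(spec)
  proto <- dock_protocol(n_min_steps = 10, n_mc_steps = 100,
                         n_anneal_steps = 200, n_independent = 1,
                         runs_per_block = 2, rng_seed = 21)
  expv <- rnorm(5, 5)
  base <- lapply(ls_$ligands, function(l) dock(l, maps, proto))
  pred0 <- lgfe_to_pic50(vapply(base, function(r) r$best_lgfe, numeric(1)))
  rep_ <- redock_evaluate(weight_vector(names(maps), 1), ls_$ligands, maps,
                          proto, expv, reference_results = base)
  expect_equal(rep_$MUE, mue(pred0, expv), tolerance = 1e-12)
  expect_equal(rep_$R, pearson_r(pred0, expv), tolerance = 1e-12)
  # identical protocol and weights: poses do not move
  expect_true(all(attr(rep_, "pose_shift") < 1e-9))
  expect_named(rep_[c("MUE", "R", "PI", "PC")], c("MUE", "R", "PI", "PC"))
})

test_that("weight YAML round trip preserves values", {
  w <- weight_vector(c("GENN", "GEND"), c(0.37, 1.82))
  path <- file.path(tempdir(), "w.yaml")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(unclass(w2), unclass(w))
})
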