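# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the implementation they check.

KB <- 0.0019872

# nearest voxel by explicit index arithmetic
oracle_gfe_at <- function(grid, xyz) {
  idx <- floor((xyz - grid$origin) / grid$spacing + 0.5) + 1
  if (any(idx < 1) || any(idx > grid$dims)) return(grid$gfe_cap)
  grid$values[idx[1], idx[2], idx[3]]
}

# nearest voxel by exhaustive search over voxel-center distances
oracle_gfe_at_scan <- function(grid, xyz) {
  best <- Inf; best_val <- NA_real_
  for (i in seq_len(grid$dims[1])) for (j in seq_len(grid$dims[2]))
    for (k in seq_len(grid$dims[3])) {
      cen <- grid$origin + (c(i, j, k) - 1) * grid$spacing
      d <- sum((xyz - cen)^2)
      if (d < best) { best <- d; best_val <- grid$values[i, j, k] }
    }
  best_val
}

# LGFE by an explicit per-atom loop
oracle_lgfe <- function(xyz, labels, maps, w) {
  total <- 0
  for (a in seq_len(nrow(xyz))) {
    lab <- labels[a]
    if (lab == "UNCLASSIFIED" || !(lab %in% names(maps))) next
    wt <- if (lab %in% names(w)) w[[lab]] else 1
    total <- total + wt * oracle_gfe_at(maps[[lab]], xyz[a, ])
  }
  total
}

# predictive index by explicit pairwise double loop
oracle_pi <- function(pred, exp) {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- abs(exp[j] - exp[i])
    dp <- pred[j] - pred[i]
    de <- exp[j] - exp[i]
    cc <- if (dp == 0) 0 else if (de * dp > 0) 1 else if (de * dp < 0) -1 else 0
    num <- num + w * cc
    den <- den + w
  }
  num / den
}

# percent correct by explicit per-reference loop (strict ties)
oracle_pc <- function(pred, exp) {
  n <- length(pred)
  pcs <- numeric(n)
  for (i in seq_len(n)) {
    good <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      se <- sign(exp[j] - exp[i]); sp <- sign(pred[j] - pred[i])
      if (se != 0 && se == sp) good <- good + 1
    }
    pcs[i] <- good / (n - 1)
  }
  mean(pcs)
}

# small random grid for lookup/scoring tests
random_grid <- function(dims = c(5L, 5L, 5L), map_type = "GENN", cap = 3) {
  vals <- array(runif(prod(dims), -5, cap), dim = dims)
  fragmap_grid(vals, origin = runif(3, -2, 0), spacing = runif(1, 0.8, 1.4),
               map_type = map_type, gfe_cap = cap)
}

# simple hand-built molecules
benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  ligand("benzene",
         atoms = data.frame(element = "C", charge = 0L, aromatic = TRUE,
                            x = 1.4 * cos(ang), y = 1.4 * sin(ang), z = 0),
         bonds = data.frame(i = 1:6, j = c(2:6, 1L),
                            order = c(1L, 2L, 1L, 2L, 1L, 2L)))
}

methanol <- function() {
  ligand("methanol",
         atoms = data.frame(
           element = c("C", "O", "H", "H", "H", "H"),
           charge = 0L, aromatic = FALSE,
           x = c(0, 1.43, 1.8, -0.5, -0.5, -0.5),
           y = c(0, 0, 0.9, 0.9, -0.9, 0),
           z = c(0, 0, 0, 0, 0, 1)),
         bonds = data.frame(i = c(1, 2, 1, 1, 1), j = c(2, 3, 4, 5, 6),
                            order = 1L))
}

methylammonium <- function() {
  ligand("methylammonium",
         atoms = data.frame(
           element = c("N", "C", "H", "H", "H"),
           charge = c(1L, 0L, 0L, 0L, 0L), aromatic = FALSE,
           x = c(0, 1.48, -0.5, -0.5, -0.5),
           y = c(0, 0, 0.9, -0.9, 0),
           z = c(0, 0, 0, 0, 0.9)),
         bonds = data.frame(i = c(1, 1, 1, 1), j = c(2, 3, 4, 5), order = 1L))
}

n_butane <- function() {
  ligand("n-butane",
         atoms = data.frame(
           element = "C", charge = 0L, aromatic = FALSE,
           x = c(0, 1.5, 2.0, 3.5),
           y = c(0, 0.3, 1.6, 1.9),
           z = c(0, 0, 0, 0)),
         bonds = data.frame(i = 1:3, j = 2:4, order = 1L))
}

ethane <- function() {
  ligand("ethane",
         atoms = data.frame(element = "C", charge = 0L, aromatic = FALSE,
                            x = c(0, 1.54), y = 0, z = 0),
         bonds = data.frame(i = 1L, j = 2L, order = 1L))
}

# uniform (flat) map set
flat_maps <- function(value, types = "GENN", dims = c(7L, 7L, 7L), cap = 3) {
  fragmap_set(lapply(types, function(tn)
    fragmap_grid(array(value, dims), origin = c(-3, -3, -3), spacing = 1,
                 map_type = tn, gfe_cap = cap)))
}
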