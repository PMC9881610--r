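#' Specification for synthetic fixtures
#'
#' Describes the synthetic study conditions: Gaussian-well FragMaps on a
#' small grid, procedurally built ligands, and affinity tables generated
#' from a known true weight vector. Every generator derives all
#' randomness from `rng_seed`, so fixtures are reproducible byte for
#' byte.
#'
#' Defaults: a 21^3 grid at 1 Angstrom spacing centered on the origin,
#' one negative Gaussian well per FragMap type (depths -6 to -4 kcal/mol,
#' width 3 Angstrom) co-located at the grid center, 20 ligands of 4-10
#' heavy atoms,
#' a deliberately non-unit true weight vector inside the optimization
#' bounds, and Gaussian pIC50 noise of 0.3 log units — the scale of
#' inter-laboratory scatter in curated hERG datasets.
#'
#' @param dims grid dimensions (3 integers).
#' @param spacing voxel spacing, Angstrom.
#' @param origin grid origin, Angstrom.
#' @param gfe_cap GFE cap / baseline, kcal/mol.
#' @param map_types FragMap-type vocabulary.
#' @param wells named list (per map type) of lists of wells, each
#'   `list(center =, depth =, width =)`; depth must be <= 0. Default one
#'   auto-placed well per type.
#' @param n_ligands number of ligands to generate.
#' @param size_range heavy-atom count range.
#' @param true_weights named true weight vector w* (inside `[0.05, 2]`).
#' @param noise_sigma Gaussian pIC50 noise, log units.
#' @param rng_seed integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dims = c(21L, 21L, 21L),
                           spacing = 1,
                           origin = c(-10, -10, -10),
                           gfe_cap = 3.0,
                           map_types = c("GENN", "GEND", "GENA", "MAMN", "ACEO"),
                           wells = NULL,
                           n_ligands = 20L,
                           size_range = c(4L, 10L),
                           true_weights = NULL,
                           noise_sigma = 0.3,
                           rng_seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 2L), spacing > 0,
            noise_sigma >= 0, size_range[1] >= 1L,
            size_range[2] >= size_range[1])
  if (is.null(wells)) {
    # one well per type, co-located at the grid center: a compact ligand
    # can then realize every atom's type signal in a single pose, so the
    # composition-derived affinities are achievable docked scores
    depths <- seq(-6, -4, length.out = length(map_types))
    wells <- setNames(lapply(seq_along(map_types), function(k)
      list(list(center = c(0, 0, 0), depth = depths[k], width = 3))),
      map_types)
  }
  for (tn in names(wells))
    for (wl in wells[[tn]])
      if (wl$depth > 0) .stopf("well depths must be <= 0 (map %s)", tn)
  if (is.null(true_weights))
    true_weights <- setNames(
      seq(0.3, 1.8, length.out = length(map_types)), map_types)
  if (any(true_weights < 0.05) || any(true_weights > 2.0))
    .stopf("true weights must lie inside [0.05, 2.0]")
  structure(list(
    dims = as.integer(dims), spacing = spacing, origin = origin,
    gfe_cap = gfe_cap, map_types = map_types, wells = wells,
    n_ligands = as.integer(n_ligands), size_range = as.integer(size_range),
    true_weights = true_weights, noise_sigma = noise_sigma,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_spec")
}

#' Generate Gaussian-well FragMaps
#'
#' Each map is a uniform baseline at `gfe_cap` plus its summed negative
#' Gaussian wells `depth * exp(-r^2 / (2 width^2))` evaluated at voxel
#' centers, then capped by the grid construction rules (negative wells
#' are never capped). Wells outside the grid bounds are an error.
#' Deterministic: the wells come from the spec, no randomness is used.
#'
#' @param spec a [synthetic_spec].
#' @return A [fragmap_set].
#' @export
make_fragmaps <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$dims
  ax <- lapply(1:3, function(a) spec$origin[a] + (seq_len(d[a]) - 1) * spec$spacing)
  hi <- spec$origin + (d - 1) * spec$spacing
  grids <- lapply(spec$map_types, function(tn) {
    vals <- array(spec$gfe_cap, dim = d)
    for (wl in spec$wells[[tn]]) {
      if (any(wl$center < spec$origin) || any(wl$center > hi))
        .stopf("well center for map %s lies outside the grid", tn)
      gx <- exp(-(ax[[1]] - wl$center[1])^2 / (2 * wl$width^2))
      gy <- exp(-(ax[[2]] - wl$center[2])^2 / (2 * wl$width^2))
      gz <- exp(-(ax[[3]] - wl$center[3])^2 / (2 * wl$width^2))
      vals <- vals + wl$depth * (gx %o% gy %o% gz)
    }
    fragmap_grid(vals, origin = spec$origin, spacing = spec$spacing,
                 map_type = tn, gfe_cap = spec$gfe_cap)
  })
  fragmap_set(grids)
}

# map a FragMap class label to (element, charge, add an H?)
.CLASS_ATOMS <- list(
  GENN = list(element = "C", charge = 0L, add_h = FALSE),
  GEND = list(element = "O", charge = 0L, add_h = TRUE),
  GENA = list(element = "O", charge = 0L, add_h = FALSE),
  MAMN = list(element = "N", charge = 1L, add_h = FALSE),
  ACEO = list(element = "O", charge = -1L, add_h = FALSE)
)

#' Build one procedural ligand with a prescribed class composition
#'
#' Grows a self-avoiding heavy-atom chain (bond length 1.5 Angstrom,
#' minimum non-bonded separation 1.9 Angstrom) whose atoms realize the
#' requested FragMap-class composition exactly: apolar carbons (`GENN`),
#' hydroxyl-like donors (`GEND`, an O with one H at 0.96 Angstrom),
#' ether-like acceptors (`GENA`), protonated nitrogens (`MAMN`) and
#' anionic oxygens (`ACEO`). Chemistry is deliberately minimal — the
#' docking and scoring machinery only ever sees class labels and
#' coordinates. Uses the current RNG state.
#'
#' @param name ligand name.
#' @param composition named integer vector, e.g. `c(GENN = 3, MAMN = 1)`.
#' @return A [ligand].
#' @export
make_ligand <- function(name, composition) {
  if (is.null(names(composition)) ||
      !all(names(composition) %in% names(.CLASS_ATOMS)))
    .stopf("composition names must be FragMap classes (%s)",
           paste(names(.CLASS_ATOMS), collapse = ", "))
  classes <- rep(names(composition), composition)
  if (length(classes) > 1L) classes <- sample(classes)
  n <- length(classes)
  xyz <- matrix(0, n, 3L)
  for (a in seq_len(n)[-1]) {
    repeat {
      cand <- xyz[a - 1L, ] + 1.5 * .random_axis()
      if (a == 2L || min(sqrt(rowSums((xyz[seq_len(a - 2L), , drop = FALSE] -
            matrix(cand, a - 2L, 3L, byrow = TRUE))^2))) > 1.9) break
    }
    xyz[a, ] <- cand
  }
  spec_at <- .CLASS_ATOMS[classes]
  atoms <- data.frame(
    element = vapply(spec_at, `[[`, character(1), "element"),
    charge = vapply(spec_at, `[[`, integer(1), "charge"),
    aromatic = FALSE,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  bonds <- if (n > 1L)
    data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L)
  else data.frame(i = integer(0), j = integer(0), order = integer(0))
  # explicit hydrogens on donor oxygens
  for (a in which(vapply(spec_at, `[[`, logical(1), "add_h"))) {
    hpos <- xyz[a, ] + 0.96 * .random_axis()
    atoms <- rbind(atoms, data.frame(element = "H", charge = 0L,
                                     aromatic = FALSE, x = hpos[1],
                                     y = hpos[2], z = hpos[3]))
    bonds <- rbind(bonds, data.frame(i = a, j = nrow(atoms), order = 1L))
  }
  ligand(name, atoms, bonds)
}

#' Generate a deterministic set of synthetic ligands
#'
#' Draws `n_ligands` class compositions (apolar-dominated with random
#' heteroatoms, sizes uniform in `size_range`) and builds each with
#' [make_ligand()]. Seeded from the spec.
#'
#' @param spec a [synthetic_spec].
#' @return List with `ligands` (list of [ligand]) and `assignments`
#'   (their [classify_atoms()] labels).
#' @export
make_ligand_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  probs <- c(GENN = 0.6, GEND = 0.1, GENA = 0.1, MAMN = 0.1, ACEO = 0.1)
  probs <- probs[names(probs) %in% spec$map_types]
  ligands <- lapply(seq_len(spec$n_ligands), function(k) {
    sizes <- spec$size_range[1]:spec$size_range[2]
    n_heavy <- sizes[sample.int(length(sizes), 1L)]
    cls <- sample(names(probs), n_heavy, replace = TRUE, prob = probs)
    comp <- table(cls)
    make_ligand(sprintf("syn_%03d", k),
                setNames(as.integer(comp), names(comp)))
  })
  assignments <- lapply(ligands, classify_atoms)
  list(ligands = ligands, assignments = assignments)
}

#' Generate a synthetic atomic-GFE table with known true weights
#'
#' Draws per-ligand, per-type unweighted GFE sums `G[i, t]` uniformly in
#' `[-5, 0]` for the types each ligand "occupies" (each type with
#' probability 0.7, at least one per ligand), and experimental pIC50
#' values `lgfe_to_pic50(sum_t w*[t] G[i, t]) + N(0, sigma)`. The true
#' weights are recorded for recovery tests.
#'
#' @param spec a [synthetic_spec] (uses `n_ligands`, `map_types`,
#'   `true_weights`, `noise_sigma`, `rng_seed`).
#' @return List with `table` (a [gfe_table]), `true_weights`, and
#'   `noiseless_pic50`.
#' @export
make_bml_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_ligands
  if (n < 1L) .stopf("empty table: n_ligands must be >= 1")
  set.seed(spec$rng_seed)
  nt <- length(spec$map_types)
  occupied <- matrix(stats::runif(n * nt) < 0.7, n, nt)
  none <- which(rowSums(occupied) == 0L)
  for (i in none) occupied[i, sample.int(nt, 1L)] <- TRUE
  G <- matrix(0, n, nt, dimnames = list(sprintf("lig_%03d", seq_len(n)),
                                        spec$map_types))
  G[occupied] <- stats::runif(sum(occupied), -5, 0)
  w <- spec$true_weights[spec$map_types]
  clean <- lgfe_to_pic50(as.vector(G %*% w))
  expv <- clean + stats::rnorm(n, 0, spec$noise_sigma)
  list(table = gfe_table(G, expv), true_weights = w,
       noiseless_pic50 = clean)
}

#' Generate a two-signal dataset for the consensus model
#'
#' Experimental pIC50 is the sum of a descriptor-driven signal (a linear
#' combination of the five physicochemical descriptors), an independent
#' structure-driven signal (the synthetic structure-based predicted
#' pIC50), and Gaussian noise. By construction, neither the
#' property-only nor the structure-only model can explain both
#' components, so the consensus model's correlation strictly exceeds
#' either on large enough samples.
#'
#' @param spec a [synthetic_spec] (uses `n_ligands`, `noise_sigma`,
#'   `rng_seed`).
#' @param descriptor_weight,structure_weight relative scales of the two
#'   signal components (pIC50 standard deviations).
#' @return List with `descriptors` (data.frame), `silcs_pic50` (named
#'   vector), `exp_pic50` (named vector).
#' @export
make_consensus_dataset <- function(spec, descriptor_weight = 1,
                                   structure_weight = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_ligands
  set.seed(spec$rng_seed + 7L)
  ids <- sprintf("cpd_%03d", seq_len(n))
  desc <- data.frame(
    compound = ids,
    logP = stats::runif(n, 0, 5),
    logS = stats::runif(n, -6, 0),
    TPSA = stats::runif(n, 20, 120),
    MW = stats::runif(n, 200, 500),
    vdw_volume = stats::runif(n, 150, 500))
  # standardized descriptor signal: higher lipophilicity, lower polarity
  z <- function(v) (v - mean(v)) / stats::sd(v)
  desc_signal <- (z(desc$logP) - 0.5 * z(desc$TPSA) + 0.3 * z(desc$MW))
  desc_signal <- desc_signal / stats::sd(desc_signal)
  struct_signal <- stats::rnorm(n)
  silcs_pic50 <- setNames(5 + struct_signal, ids)
  expv <- setNames(5 + descriptor_weight * desc_signal +
                     structure_weight * struct_signal +
                     stats::rnorm(n, 0, spec$noise_sigma), ids)
  list(descriptors = desc, silcs_pic50 = silcs_pic50, exp_pic50 = expv)
}

#' Write a complete synthetic fixture directory
#'
#' Emits everything the pipeline consumes, in its standard formats:
#' FragMaps as OpenDX (`maps/<prefix>.<type>.dx`), ligands as SDF
#' (charged states as separate `<id>.charged` records), the affinity
#' table, descriptor table and pKa table as CSV. The affinity ground
#' truth is derived from the true weights and each ligand's class
#' composition against the well depths, plus Gaussian noise.
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory.
#' @return Invisibly, a list of the written paths.
#' @export
write_synthetic_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- make_fragmaps(spec)
  map_paths <- write_fragmap_dir(maps, file.path(dir, "maps"), prefix = "syn")
  ls_ <- make_ligand_set(spec)
  set.seed(spec$rng_seed + 13L)
  # charged variants: demote each MAMN nitrogen to neutral for the pair
  ligs <- ls_$ligands
  pka <- data.frame(compound = character(0), pKa = numeric(0),
                    kind = character(0))
  all_records <- list()
  for (lig in ligs) {
    has_charge <- any(lig$atoms$charge != 0L)
    if (has_charge) {
      neutral <- lig
      neutral$atoms$charge <- 0L
      neutral$name <- lig$name
      charged <- lig
      charged$name <- paste0(lig$name, ".charged")
      charged$ionization_state <- "charged"
      all_records <- c(all_records, list(neutral, charged))
      pka <- rbind(pka, data.frame(compound = lig$name,
                                   pKa = round(stats::runif(1, 6.5, 9.5), 2),
                                   kind = "base"))
    } else {
      all_records <- c(all_records, list(lig))
    }
  }
  sdf_path <- file.path(dir, "ligands.sdf")
  write_sdf(all_records, sdf_path)
  # affinity ground truth from class composition x well depth x true weight
  depth_at_center <- vapply(spec$map_types, function(tn)
    spec$gfe_cap + sum(vapply(spec$wells[[tn]], `[[`, numeric(1), "depth")),
    numeric(1))
  expv <- vapply(seq_along(ligs), function(k) {
    labs <- ls_$assignments[[k]]
    s <- 0
    for (tn in spec$map_types)
      s <- s + spec$true_weights[[tn]] * sum(labs == tn) * depth_at_center[[tn]]
    lgfe_to_pic50(s)
  }, numeric(1))
  expv <- expv + stats::rnorm(length(expv), 0, spec$noise_sigma)
  aff <- data.frame(compound = vapply(ligs, function(l) l$name, character(1)),
                    exp_pic50 = expv)
  aff_path <- file.path(dir, "affinities.csv")
  write.csv(aff, aff_path, row.names = FALSE)
  # descriptors correlated with composition + noise, so the consensus
  # model has an independent property channel
  nheavy <- vapply(ligs, function(l) sum(l$atoms$element != "H"), numeric(1))
  desc <- data.frame(
    compound = aff$compound,
    logP = round(0.5 * nheavy + stats::rnorm(length(ligs), 0, 0.5), 3),
    logS = round(-0.4 * nheavy + stats::rnorm(length(ligs), 0, 0.5), 3),
    TPSA = round(20 + 10 * vapply(ligs, function(l)
      sum(l$atoms$element %in% c("N", "O")), numeric(1)) +
        stats::rnorm(length(ligs), 0, 2), 2),
    MW = round(13 * nheavy + stats::rnorm(length(ligs), 0, 5), 2),
    vdw_volume = round(20 * nheavy + stats::rnorm(length(ligs), 0, 10), 2))
  desc_path <- file.path(dir, "descriptors.csv")
  write.csv(desc, desc_path, row.names = FALSE)
  pka_path <- file.path(dir, "pka.csv")
  write.csv(pka, pka_path, row.names = FALSE)
  invisible(list(maps = map_paths, sdf = sdf_path, affinities = aff_path,
                 descriptors = desc_path, pka = pka_path))
}
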