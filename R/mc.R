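#' Docking protocol parameters
#'
#' Bundles every knob of the Monte-Carlo docking protocol. The defaults
#' follow the production protocol for FragMap docking: random placement
#' within a 10 Angstrom radius of the pocket center, 10,000 greedy
#' minimization steps, 10,000 Metropolis MC steps at 300 K, 40,000
#' simulated-annealing steps cooling linearly from 300 K to 0 K, five
#' independent simulations of up to 50 runs each, convergence when the
#' two lowest run scores agree within 0.5 kcal/mol, and a hard cap of 250
#' runs.
#'
#' @param pocket_center numeric length-3, pocket center (Angstrom).
#' @param placement_radius radius of the random-placement sphere, Angstrom.
#' @param n_min_steps greedy (downhill-only) minimization steps.
#' @param n_mc_steps fixed-temperature Metropolis MC steps.
#' @param T_mc MC temperature, K.
#' @param n_anneal_steps simulated-annealing steps.
#' @param T_anneal_start,T_anneal_end annealing temperature endpoints, K.
#' @param n_independent number of independent simulation blocks.
#' @param runs_per_block maximum runs per block.
#' @param convergence_tol convergence tolerance on the two lowest run
#'   scores, kcal/mol.
#' @param max_runs hard cap on total runs.
#' @param max_translation,max_rotation,max_torsion move amplitudes
#'   (Angstrom, radians, radians).
#' @param rng_seed integer seed; every run derives its own substream so
#'   results are reproducible run-by-run.
#' @return Object of class `dock_protocol`.
#' @export
dock_protocol <- function(pocket_center = c(0, 0, 0),
                          placement_radius = 10,
                          n_min_steps = 10000,
                          n_mc_steps = 10000,
                          T_mc = 300,
                          n_anneal_steps = 40000,
                          T_anneal_start = 300,
                          T_anneal_end = 0,
                          n_independent = 5,
                          runs_per_block = 50,
                          convergence_tol = 0.5,
                          max_runs = 250,
                          max_translation = 1.0,
                          max_rotation = 0.25,
                          max_torsion = 0.5,
                          rng_seed = 1L) {
  stopifnot(length(pocket_center) == 3L, placement_radius > 0,
            n_min_steps >= 0, n_mc_steps >= 0, n_anneal_steps >= 0,
            T_mc >= 0, T_anneal_end <= T_anneal_start,
            n_independent >= 1, runs_per_block >= 1,
            convergence_tol > 0, max_runs >= 1,
            max_translation > 0, max_rotation > 0, max_torsion > 0)
  structure(as.list(environment()), class = "dock_protocol")
}

#' Metropolis acceptance test
#'
#' Accepts downhill moves always; uphill moves with probability
#' `exp(-delta_e / (kB * T))`. At `T = 0` only downhill (or neutral)
#' moves are accepted. Vectorized over `delta_e`.
#'
#' @param delta_e energy change(s), kcal/mol.
#' @param temperature temperature, K (>= 0).
#' @return Logical vector of acceptance flags.
#' @export
metropolis <- function(delta_e, temperature) {
  if (temperature < 0) .stopf("'temperature' must be >= 0")
  accept <- delta_e <= 0
  up <- which(!accept)
  if (length(up) > 0L)
    accept[up] <- stats::runif(length(up)) <
      exp(-delta_e[up] / (.kB * temperature))
  accept
}

# uniform random rotation matrix (Shoemake quaternion method)
.random_rotation_matrix <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Random initial placement of a ligand
#'
#' Places the ligand centroid uniformly at random inside the sphere
#' (pocket center, placement radius) with a uniformly random rigid
#' orientation; internal geometry is unchanged. Uses the current RNG
#' state (seed it for reproducibility).
#'
#' @param lig a [ligand].
#' @param protocol a [dock_protocol].
#' @return A [conformer].
#' @export
random_placement <- function(lig, protocol) {
  stopifnot(inherits(lig, "ligand"), inherits(protocol, "dock_protocol"))
  xyz <- coords(lig)
  cen <- colMeans(xyz)
  xyz <- (xyz - matrix(cen, nrow(xyz), 3L, byrow = TRUE)) %*%
    t(.random_rotation_matrix())
  r <- protocol$placement_radius * stats::runif(1)^(1 / 3)
  target <- protocol$pocket_center + r * .random_axis()
  conformer(lig, xyz + matrix(target, nrow(xyz), 3L, byrow = TRUE))
}

# one MC move on a coordinate matrix; returns the new matrix.
# move types: 1 translate, 2 rigid rotate, 3 torsion (if torsions exist)
.propose <- function(xyz, torsions, max_t, max_r, max_d) {
  n_types <- if (length(torsions) > 0L) 3L else 2L
  type <- floor(stats::runif(1) * n_types) + 1L
  if (type == 1L) {
    shift <- stats::runif(3, -max_t, max_t)
    xyz + matrix(shift, nrow(xyz), 3L, byrow = TRUE)
  } else if (type == 2L) {
    cen <- colMeans(xyz)
    R <- .rotation_matrix(.random_axis(), stats::runif(1, -max_r, max_r))
    sweep(sweep(xyz, 2L, cen) %*% t(R), 2L, cen, "+")
  } else {
    tor <- torsions[[floor(stats::runif(1) * length(torsions)) + 1L]]
    axis <- xyz[tor$k, ] - xyz[tor$j, ]
    R <- .rotation_matrix(axis, stats::runif(1, -max_d, max_d))
    pivot <- xyz[tor$j, ]
    mov <- tor$movable
    xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2L, pivot) %*% t(R),
                        2L, pivot, "+")
    xyz
  }
}

#' Propose a single Monte-Carlo move
#'
#' Chooses uniformly among translation, rigid rotation and (when
#' rotatable bonds exist) torsion rotation, each perturbed uniformly
#' within its amplitude. Translations and rotations preserve all
#' interatomic distances; torsions move only the atoms on the rotated
#' side of the bond.
#'
#' @param conf a [conformer].
#' @param torsions torsion list from [rotatable_bonds()]; default derived
#'   from the parent ligand.
#' @param max_translation,max_rotation,max_torsion move amplitudes
#'   (Angstrom, radians, radians).
#' @return A new [conformer].
#' @export
propose_move <- function(conf, torsions = rotatable_bonds(conf$parent),
                         max_translation = 1.0, max_rotation = 0.25,
                         max_torsion = 0.5) {
  stopifnot(inherits(conf, "conformer"))
  conformer(conf$parent,
            .propose(conf$xyz, torsions, max_translation, max_rotation,
                     max_torsion))
}

# precompute a fast LGFE evaluator for fixed assignment/maps/weights
.make_energy <- function(assignment, maps, w) {
  labs <- setdiff(unique(as.character(assignment)), "UNCLASSIFIED")
  missing <- setdiff(labs, names(maps))
  if (length(missing) > 0L)
    .warnf("no FragMap for type(s) %s; those atoms contribute 0",
           paste(missing, collapse = ", "))
  labs <- intersect(labs, names(maps))
  grids <- lapply(labs, function(l) maps[[l]])
  idxs <- lapply(labs, function(l) which(assignment == l))
  wts <- unname(vapply(labs, function(l) .weight_for(w, l), numeric(1)))
  nl <- length(labs)
  function(xyz) {
    e <- 0
    for (t in seq_len(nl))
      e <- e + wts[t] * sum(.gfe_lookup(grids[[t]], xyz[idxs[[t]], , drop = FALSE]))
    e
  }
}

#' One docking run: placement, minimization, MC, simulated annealing
#'
#' Executes a single run of the docking protocol: random placement, then
#' `n_min_steps` greedy moves (accepted only when the energy decreases; a
#' grid-field stand-in for force-field pre-minimization), then
#' `n_mc_steps` Metropolis MC at `T_mc`, then `n_anneal_steps` with the
#' temperature lowered linearly from `T_anneal_start` to `T_anneal_end`.
#' Returns the lowest-energy pose seen at any point. Uses the current RNG
#' state.
#'
#' @param lig a [ligand].
#' @param maps a [fragmap_set].
#' @param assignment labels from [classify_atoms()]; default computed.
#' @param w a [weight_vector] or NULL for unit weights.
#' @param protocol a [dock_protocol].
#' @param intramolecular optional callback `function(xyz) -> kcal/mol`
#'   added to the grid energy (e.g. a force-field strain term); NULL for
#'   pure grid scoring.
#' @return List with `conformer` (best pose), `lgfe` (its grid score,
#'   kcal/mol) and `energy` (grid + intramolecular, equal to `lgfe` when
#'   no callback is used).
#' @export
anneal_run <- function(lig, maps, assignment = classify_atoms(lig), w = NULL,
                       protocol = dock_protocol(), intramolecular = NULL) {
  stopifnot(inherits(lig, "ligand"), inherits(maps, "fragmap_set"))
  grid_e <- .make_energy(assignment, maps, w)
  energy <- if (is.null(intramolecular)) grid_e else
    function(xyz) grid_e(xyz) + intramolecular(xyz)
  torsions <- rotatable_bonds(lig)
  mt <- protocol$max_translation; mr <- protocol$max_rotation
  md <- protocol$max_torsion
  center <- protocol$pocket_center
  r2max <- protocol$placement_radius^2
  xyz <- random_placement(lig, protocol)$xyz
  e <- energy(xyz)
  best_xyz <- xyz; best_e <- e
  step_once <- function(temperature) {
    cand <- .propose(xyz, torsions, mt, mr, md)
    # sampling is confined to the docking site: moves that take the
    # centroid outside the placement sphere are rejected outright
    if (sum((colMeans(cand) - center)^2) > r2max) return(invisible())
    e_cand <- energy(cand)
    ok <- if (is.null(temperature)) e_cand < e else
      metropolis(e_cand - e, temperature)
    if (ok) {
      xyz <<- cand; e <<- e_cand
      if (e < best_e) { best_xyz <<- xyz; best_e <<- e }
    }
  }
  for (s in seq_len(protocol$n_min_steps)) step_once(NULL)
  for (s in seq_len(protocol$n_mc_steps)) step_once(protocol$T_mc)
  n_ann <- protocol$n_anneal_steps
  if (n_ann > 0L) {
    dT <- (protocol$T_anneal_end - protocol$T_anneal_start) / n_ann
    for (s in seq_len(n_ann))
      step_once(protocol$T_anneal_start + dT * s)
  }
  best_conf <- conformer(lig, best_xyz)
  list(conformer = best_conf, lgfe = grid_e(best_xyz), energy = best_e)
}

#' Dock a ligand (or ionization pair) into a FragMap field
#'
#' Runs [anneal_run()] repeatedly in `n_independent` blocks of up to
#' `runs_per_block` runs, stopping early once the two lowest run scores
#' agree within `convergence_tol` (and unconditionally at `max_runs`).
#' The reported pose is the global best over all executed runs. Each run
#' is seeded deterministically from `protocol$rng_seed`, the block index
#' and the run index, so identical inputs give bit-identical results.
#'
#' For an [ionization_pair()], both states are docked and a list
#' `list(neutral = , charged = )` is returned.
#'
#' @param x a [ligand] or [ionization_pair].
#' @param maps a [fragmap_set].
#' @param protocol a [dock_protocol].
#' @param w a [weight_vector] or NULL for unit weights.
#' @param rules classification rule table.
#' @param site_label label for the docking site (e.g. `"S1"`, `"S2"`).
#' @param intramolecular optional energy callback, see [anneal_run()].
#' @return Object of class `dock_result`: `best_conformer`, `best_lgfe`,
#'   `breakdown` (per-atom GFEs of the best pose), `site_label`,
#'   `runs_executed`, `converged`, `run_lgfes`.
#' @export
dock <- function(x, maps, protocol = dock_protocol(), w = NULL,
                 rules = default_classification_rules(),
                 site_label = "S1", intramolecular = NULL) {
  if (inherits(x, "ionization_pair")) {
    return(list(
      neutral = dock(x$neutral, maps, protocol, w, rules, site_label,
                     intramolecular),
      charged = dock(x$charged, maps, protocol, w, rules, site_label,
                     intramolecular)))
  }
  stopifnot(inherits(x, "ligand"))
  assignment <- classify_atoms(x, rules)
  base_seed <- as.numeric(protocol$rng_seed)
  run_lgfes <- numeric(0)
  best <- NULL
  converged <- FALSE
  total_runs <- 0L
  for (b in seq_len(protocol$n_independent)) {
    for (r in seq_len(protocol$runs_per_block)) {
      run_id <- (b - 1L) * protocol$runs_per_block + (r - 1L)
      set.seed((base_seed + 1000003 * run_id) %% 2147483647)
      res <- anneal_run(x, maps, assignment, w, protocol, intramolecular)
      total_runs <- total_runs + 1L
      run_lgfes <- c(run_lgfes, res$lgfe)
      if (is.null(best) || res$energy < best$energy) best <- res
      if (length(run_lgfes) >= 2L) {
        two <- sort(run_lgfes)[1:2]
        if (diff(two) <= protocol$convergence_tol) converged <- TRUE
      }
      if (converged || total_runs >= protocol$max_runs) break
    }
    if (converged || total_runs >= protocol$max_runs) break
  }
  structure(list(
    ligand_name = x$name,
    best_conformer = best$conformer,
    best_lgfe = best$lgfe,
    breakdown = atomic_gfes(best$conformer, assignment, maps, w),
    site_label = site_label,
    runs_executed = total_runs,
    converged = converged,
    run_lgfes = run_lgfes
  ), class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("<dock_result> %s @ %s: LGFE %.3f kcal/mol (%d runs, %s)\n",
              x$ligand_name, x$site_label, x$best_lgfe, x$runs_executed,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
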