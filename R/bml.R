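#' Per-ligand, per-FragMap-type atomic GFE table
#'
#' The table stores, for each ligand, the unweighted sum of atomic GFEs
#' attributed to each FragMap type at a fixed docked pose, together with
#' the experimental pIC50. Because the pose score is exactly linear in
#' the per-type weights, `LGFE_i(w) = sum_t w[t] * G[i, t]`, the table
#' lets the reweighting chain re-score every ligand with a matrix product
#' instead of a redock.
#'
#' @param G n_ligands x n_types numeric matrix of unweighted per-type GFE
#'   sums (kcal/mol); column names are the FragMap types.
#' @param exp_pic50 numeric vector of experimental pIC50 values.
#' @param ligand_names optional identifiers (row names).
#' @return Object of class `gfe_table`.
#' @export
gfe_table <- function(G, exp_pic50, ligand_names = rownames(G)) {
  G <- as.matrix(G)
  if (nrow(G) == 0L) .stopf("empty atomic-GFE table")
  if (is.null(colnames(G))) .stopf("'G' must have FragMap types as column names")
  if (length(exp_pic50) != nrow(G))
    .stopf("exp_pic50 length %d does not match %d ligands",
           length(exp_pic50), nrow(G))
  if (!all(is.finite(G)) || !all(is.finite(exp_pic50)))
    .stopf("table entries must be finite")
  if (is.null(ligand_names)) ligand_names <- sprintf("lig_%d", seq_len(nrow(G)))
  rownames(G) <- ligand_names
  structure(list(G = G, exp_pic50 = as.numeric(exp_pic50),
                 map_types = colnames(G)), class = "gfe_table")
}

#' Build an atomic-GFE table from docked poses
#'
#' Decomposes each dock result's best pose into unweighted per-type GFE
#' sums (the stored breakdown is divided by the weights it was scored
#' with, so the table is weight-free).
#'
#' @param results list of `dock_result` objects (one per ligand).
#' @param maps the [fragmap_set] the results were docked into.
#' @param exp_pic50 experimental pIC50 vector aligned with `results`.
#' @param rules classification rule table.
#' @return A [gfe_table].
#' @export
build_gfe_table <- function(results, maps, exp_pic50,
                            rules = default_classification_rules()) {
  types <- names(maps)
  G <- matrix(0, length(results), length(types),
              dimnames = list(vapply(results, function(r) r$ligand_name,
                                     character(1)), types))
  for (k in seq_along(results)) {
    res <- results[[k]]
    assignment <- classify_atoms(res$best_conformer$parent, rules)
    bd <- atomic_gfes(res$best_conformer, assignment, maps, w = NULL)
    for (t in types)
      G[k, t] <- sum(bd$per_atom[bd$labels == t])
  }
  gfe_table(G, exp_pic50)
}

#' Configuration for MCSA weight optimization
#'
#' The weights are bounded by a flat-bottom potential: zero penalty
#' inside `[lower, upper]`, quadratic with force constant `k_flat`
#' outside. Defaults: `k_flat` 5000 kcal/mol, bounds 0.05 and 2.0.
#'
#' @param k_flat flat-bottom force constant (kcal/mol).
#' @param lower,upper weight bounds.
#' @param target_metric `"pearson_r"` or `"percent_correct"` — the metric
#'   the chain maximizes against the experimental affinities.
#' @param n_steps chain length.
#' @param proposal_width half-width of the uniform single-weight
#'   perturbation.
#' @param T_start,T_end effective-temperature endpoints of the geometric
#'   annealing schedule (dimensionless, loss units).
#' @param rng_seed integer seed.
#' @return Object of class `bml_config`.
#' @export
bml_config <- function(k_flat = 5000, lower = 0.05, upper = 2.0,
                       target_metric = c("pearson_r", "percent_correct"),
                       n_steps = 50000, proposal_width = 0.05,
                       T_start = 1.0, T_end = 0.01, rng_seed = 1L) {
  target_metric <- match.arg(target_metric)
  stopifnot(k_flat >= 0, lower < upper, n_steps >= 0, proposal_width > 0,
            T_start > 0, T_end > 0, T_end <= T_start)
  structure(as.list(environment()), class = "bml_config")
}

#' Flat-bottom bound penalty on a weight vector
#'
#' `sum_t k_flat * max(0, w[t] - upper)^2 + k_flat * max(0, lower -
#' w[t])^2`; exactly zero when every weight lies inside the bounds.
#'
#' @param w numeric weight vector.
#' @param cfg a [bml_config].
#' @return Penalty in kcal/mol.
#' @export
flat_bottom_penalty <- function(w, cfg = bml_config()) {
  over <- pmax(0, w - cfg$upper)
  under <- pmax(0, cfg$lower - w)
  cfg$k_flat * sum(over^2 + under^2)
}

#' MCSA objective for a weight vector
#'
#' The loss is the negated target metric of the weighted predictions
#' against the experimental pIC50s, plus the flat-bottom penalty:
#' minimizing it maximizes the metric within the bounds. Predictions are
#' `lgfe_to_pic50(G %*% w)`.
#'
#' @param w numeric weight vector (aligned with the table's map types).
#' @param table a [gfe_table].
#' @param cfg a [bml_config].
#' @return Scalar loss.
#' @export
bml_objective <- function(w, table, cfg = bml_config()) {
  stopifnot(inherits(table, "gfe_table"))
  pred <- lgfe_to_pic50(as.vector(table$G %*% w))
  metric <- if (cfg$target_metric == "pearson_r") {
    if (stats::sd(pred) == 0 || stats::sd(table$exp_pic50) == 0) {
      .warnf("zero-variance predictions in bml_objective; metric = 0")
      0
    } else stats::cor(pred, table$exp_pic50)
  } else {
    percent_correct(pred, table$exp_pic50)
  }
  -metric + flat_bottom_penalty(w, cfg)
}

#' Optimize FragMap weights by MC simulated annealing
#'
#' Markov-chain Monte-Carlo simulated annealing over the weight vector:
#' starting from unit weights, each step perturbs one randomly chosen
#' weight uniformly within the proposal width and applies a Metropolis
#' test on the loss at a geometrically decaying effective temperature.
#' Returns the best-loss weights seen. The flat-bottom penalty confines
#' the returned weights to the bounds up to an excursion of order
#' `sqrt(1 / k_flat)` (0.014 at the default force constant); larger
#' violations are reported with a warning.
#'
#' @param table a [gfe_table].
#' @param cfg a [bml_config].
#' @return A [weight_vector] with attributes `loss` (best loss) and
#'   `metric` (the achieved target metric).
#' @export
mcsa_optimize <- function(table, cfg = bml_config()) {
  stopifnot(inherits(table, "gfe_table"))
  nt <- length(table$map_types)
  set.seed(cfg$rng_seed %% 2147483647)
  w <- rep(1, nt)
  loss <- bml_objective(w, table, cfg)
  best_w <- w; best_loss <- loss
  n <- cfg$n_steps
  if (n > 0L) {
    decay <- (cfg$T_end / cfg$T_start)^(1 / n)
    temp <- cfg$T_start
    for (s in seq_len(n)) {
      t_idx <- floor(stats::runif(1) * nt) + 1L
      cand <- w
      cand[t_idx] <- cand[t_idx] +
        stats::runif(1, -cfg$proposal_width, cfg$proposal_width)
      cand_loss <- bml_objective(cand, table, cfg)
      d <- cand_loss - loss
      if (d <= 0 || stats::runif(1) < exp(-d / temp)) {
        w <- cand; loss <- cand_loss
        if (loss < best_loss) { best_w <- w; best_loss <- loss }
      }
      temp <- temp * decay
    }
  }
  eps <- if (cfg$k_flat > 0) sqrt(1 / cfg$k_flat) else Inf
  if (any(best_w > cfg$upper + eps) || any(best_w < cfg$lower - eps))
    .warnf("optimized weights violate the flat-bottom bounds beyond %g", eps)
  out <- weight_vector(table$map_types, best_w)
  attr(out, "loss") <- best_loss
  attr(out, "metric") <- -(best_loss - flat_bottom_penalty(best_w, cfg))
  out
}

#' Redock under optimized weights and evaluate
#'
#' The finalization step of weight optimization: every ligand is fully
#' redocked with the new weights (poses may move), the redocked scores
#' are converted to pIC50, and the metrics are computed against
#' experiment. A pose-shift diagnostic (centroid displacement vs the
#' reference poses, Angstrom) is attached as an overfitting sentinel:
#' weights that only look good because they distort poses show large
#' shifts.
#'
#' @param w a [weight_vector].
#' @param ligands list of [ligand] objects.
#' @param maps a [fragmap_set].
#' @param protocol a [dock_protocol].
#' @param exp_pic50 experimental pIC50 vector aligned with `ligands`.
#' @param reference_results optional list of `dock_result` objects from
#'   the original docking, for the pose-shift diagnostic.
#' @param rules classification rule table.
#' @return A [metrics_report()] with attributes `results` (the redock
#'   results) and `pose_shift` (per-ligand centroid displacement, or NULL).
#' @export
redock_evaluate <- function(w, ligands, maps, protocol, exp_pic50,
                            reference_results = NULL,
                            rules = default_classification_rules()) {
  results <- vector("list", length(ligands))
  ok <- logical(length(ligands))
  for (k in seq_along(ligands)) {
    results[[k]] <- tryCatch(
      dock(ligands[[k]], maps, protocol, w, rules),
      error = function(e) {
        .warnf("redock of '%s' failed (%s); excluded", ligands[[k]]$name,
               conditionMessage(e))
        NULL
      })
    ok[k] <- !is.null(results[[k]])
  }
  if (!any(ok)) .stopf("all redocks failed")
  pred <- lgfe_to_pic50(vapply(results[ok], function(r) r$best_lgfe, numeric(1)))
  rep_ <- metrics_report(pred, exp_pic50[ok])
  shift <- NULL
  if (!is.null(reference_results)) {
    shift <- vapply(which(ok), function(k) {
      a <- colMeans(results[[k]]$best_conformer$xyz)
      b <- colMeans(reference_results[[k]]$best_conformer$xyz)
      sqrt(sum((a - b)^2))
    }, numeric(1))
  }
  attr(rep_, "results") <- results[ok]
  attr(rep_, "pose_shift") <- shift
  rep_
}

#' Read / write weight vectors as YAML
#'
#' @param w a [weight_vector].
#' @param path YAML path.
#' @return The weights ([read_weights]) or `path` invisibly
#'   ([write_weights]).
#' @export
write_weights <- function(w, path) {
  yaml::write_yaml(as.list(unclass(w)), path, precision = 17)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lst <- yaml::read_yaml(path)
  weight_vector(names(lst), unlist(lst))
}
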