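#' Per-FragMap-type weight vector
#'
#' Multiplicative weights applied to each FragMap type's contribution to
#' the ligand grid free energy. Unit weights reproduce the unweighted
#' score; the MCSA reweighting returns an optimized vector.
#'
#' @param map_types character vector of FragMap-type labels.
#' @param values numeric weights (recycled), default 1.
#' @return Named numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(map_types, values = 1) {
  w <- rep_len(as.numeric(values), length(map_types))
  if (any(!is.finite(w)) || any(w < 0))
    .stopf("weights must be finite and nonnegative")
  structure(setNames(w, map_types), class = "weight_vector")
}

# resolve a weight for a label: named entry if present else 1
.weight_for <- function(w, label) {
  if (is.null(w)) return(1)
  if (label %in% names(w)) unname(w[[label]]) else 1
}

#' Per-atom GFE breakdown of a pose
#'
#' Looks up, for every classified heavy atom, the GFE of the voxel it
#' occupies in the FragMap of its assigned type, scaled by that type's
#' weight. `UNCLASSIFIED` atoms (including all hydrogens) contribute 0;
#' atoms whose label has no grid in `maps` contribute 0 with a warning.
#' The total LGFE is the exact sum of the per-atom entries.
#'
#' @param conf a [conformer] (or [ligand], used at its own coordinates).
#' @param assignment per-atom labels from [classify_atoms()].
#' @param maps a [fragmap_set].
#' @param w a [weight_vector] (default: unit weight for every type).
#' @return Object of class `gfe_breakdown`: list with `per_atom` (numeric
#'   vector, kcal/mol), `labels`, and `total` (LGFE, kcal/mol).
#' @export
atomic_gfes <- function(conf, assignment, maps, w = NULL) {
  if (inherits(conf, "ligand")) conf <- conformer(conf)
  stopifnot(inherits(conf, "conformer"), inherits(maps, "fragmap_set"))
  n <- nrow(conf$xyz)
  if (length(assignment) != n)
    .stopf("assignment length %d does not match %d atoms", length(assignment), n)
  per_atom <- numeric(n)
  for (lab in setdiff(unique(assignment), "UNCLASSIFIED")) {
    idx <- which(assignment == lab)
    if (!(lab %in% names(maps))) {
      .warnf("no FragMap for type '%s'; %d atom(s) contribute 0", lab, length(idx))
      next
    }
    per_atom[idx] <- .weight_for(w, lab) *
      .gfe_lookup(maps[[lab]], conf$xyz[idx, , drop = FALSE])
  }
  structure(list(per_atom = per_atom, labels = as.character(assignment),
                 total = sum(per_atom)), class = "gfe_breakdown")
}

#' Ligand grid free energy of a pose
#'
#' The LGFE is the summation of the atomic GFE scores; see
#' [atomic_gfes()].
#'
#' @inheritParams atomic_gfes
#' @return LGFE in kcal/mol.
#' @export
lgfe <- function(conf, assignment, maps, w = NULL) {
  atomic_gfes(conf, assignment, maps, w)$total
}

#' Group (moiety) sums of a GFE breakdown
#'
#' Sums per-atom GFEs over named atom sets, e.g. to report the free-energy
#' contribution of a ring or substituent. Over a partition of all atoms
#' the group sums reproduce the total LGFE exactly.
#'
#' @param breakdown a `gfe_breakdown` from [atomic_gfes()].
#' @param groups named list of integer atom-index vectors.
#' @return Named numeric vector of group GFE sums (kcal/mol).
#' @export
group_gfe_sums <- function(breakdown, groups) {
  stopifnot(inherits(breakdown, "gfe_breakdown"))
  vapply(groups, function(idx) sum(breakdown$per_atom[idx]), numeric(1))
}

#' Fraction of the charged species at a given pH
#'
#' Henderson-Hasselbalch: for a base the charged (protonated) fraction is
#' `1 / (1 + 10^(pH - pKa))`; for an acid the charged (deprotonated)
#' fraction is `1 / (1 + 10^(pKa - pH))`.
#'
#' @param pKa numeric pKa.
#' @param pH numeric pH (default 7.4, physiological).
#' @param kind `"base"` or `"acid"`.
#' @return Charged fraction in `[0, 1]`.
#' @export
charged_fraction <- function(pKa, pH = 7.4, kind = c("base", "acid")) {
  kind <- match.arg(kind)
  if (!is.numeric(pKa) || !is.numeric(pH) || anyNA(pKa) || anyNA(pH))
    .stopf("'pKa' and 'pH' must be numeric")
  if (kind == "base") 1 / (1 + 10^(pH - pKa)) else 1 / (1 + 10^(pKa - pH))
}

#' Ionization-state-weighted LGFE
#'
#' Mixes the LGFE scores of the neutral and charged states of a compound
#' by their Henderson-Hasselbalch population fractions at the given pH:
#' `f_charged * LGFE_charged + (1 - f_charged) * LGFE_neutral`. The result
#' always lies between the two state scores.
#'
#' @param lgfe_neutral,lgfe_charged state LGFE scores, kcal/mol.
#' @param pKa pKa of the ionizable group.
#' @param pH pH, default 7.4.
#' @param kind `"base"` or `"acid"`.
#' @return Weighted LGFE, kcal/mol.
#' @export
hh_weighted_lgfe <- function(lgfe_neutral, lgfe_charged, pKa, pH = 7.4,
                             kind = c("base", "acid")) {
  kind <- match.arg(kind)
  if (!all(is.finite(c(lgfe_neutral, lgfe_charged))))
    .stopf("LGFE inputs must be finite")
  f <- charged_fraction(pKa, pH, kind)
  f * lgfe_charged + (1 - f) * lgfe_neutral
}

#' Convert an LGFE score to a predicted pIC50
#'
#' `"thermodynamic"` mode treats the LGFE as a binding free energy:
#' `pIC50 = -LGFE / (ln(10) * kB * T)` (denominator 1.3727 kcal/mol at
#' 300 K). `"affine"` mode applies a user-calibrated linear map
#' `a * (-LGFE) + b`, for workflows that fit the conversion on a training
#' set instead.
#'
#' @param lgfe LGFE score(s), kcal/mol (vectorized).
#' @param mode `"thermodynamic"` or `"affine"`.
#' @param temperature temperature in K for thermodynamic mode.
#' @param a,b slope and intercept for affine mode.
#' @return Predicted pIC50 value(s).
#' @export
lgfe_to_pic50 <- function(lgfe, mode = c("thermodynamic", "affine"),
                          temperature = 300, a = 1, b = 0) {
  mode <- match.arg(mode)
  if (!all(is.finite(lgfe))) .stopf("LGFE must be finite")
  if (mode == "thermodynamic") -lgfe / (log(10) * .kB * temperature)
  else a * (-lgfe) + b
}
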