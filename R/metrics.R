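#' Mean unsigned error
#'
#' @param pred,exp numeric vectors of predicted and experimental values
#'   (pIC50 log units), equal length.
#' @return Mean of `|pred - exp|`.
#' @export
mue <- function(pred, exp) {
  if (length(pred) != length(exp)) .stopf("length mismatch: %d vs %d",
                                          length(pred), length(exp))
  if (length(pred) < 1L) .stopf("need at least one value")
  mean(abs(pred - exp))
}

#' Pearson correlation with a zero-variance guard
#'
#' Standard product-moment correlation. If either vector has zero
#' variance the correlation is undefined; this returns 0 with a warning
#' instead of NaN so that optimization objectives built on it stay
#' finite.
#'
#' @inheritParams mue
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(pred, exp) {
  if (length(pred) != length(exp)) .stopf("length mismatch: %d vs %d",
                                          length(pred), length(exp))
  if (length(pred) < 3L) .stopf("need at least 3 values for a correlation")
  if (stats::sd(pred) == 0 || stats::sd(exp) == 0) {
    .warnf("zero-variance input to pearson_r; returning 0")
    return(0)
  }
  stats::cor(pred, exp)
}

#' Predictive index
#'
#' Experimental-difference-weighted pairwise rank concordance:
#' `PI = sum_{i<j} w_ij c_ij / sum_{i<j} w_ij` with
#' `w_ij = |exp_j - exp_i|` and `c_ij = +1` when the predicted and
#' experimental differences have the same sign, `-1` when opposite, and
#' `0` when the predicted difference is zero. Pairs with equal
#' experimental values carry zero weight. PI is 1 for perfectly
#' rank-ordered predictions, -1 for a fully inverted ranking, and 0 for
#' random predictions.
#'
#' @inheritParams mue
#' @return PI in `[-1, 1]`.
#' @export
predictive_index <- function(pred, exp) {
  if (length(pred) != length(exp)) .stopf("length mismatch: %d vs %d",
                                          length(pred), length(exp))
  if (length(pred) < 2L) .stopf("need at least 2 values")
  de <- outer(exp, exp, "-")
  dp <- outer(pred, pred, "-")
  up <- upper.tri(de)
  w <- abs(de[up])
  if (sum(w) == 0) .stopf("all experimental values equal; PI undefined")
  cc <- sign(de[up]) * sign(dp[up])
  sum(w * cc) / sum(w)
}

#' Percent correct
#'
#' For each compound taken as the reference, the fraction of the
#' remaining compounds whose predicted ordering relative to the reference
#' matches the experimental ordering; the reported PC is the mean over
#' all references. Ties (in either vector) count as incorrect under the
#' default `"strict"` convention, or as half-correct under
#' `"half-credit"`. Random predictions score 0.5.
#'
#' @inheritParams mue
#' @param ties `"strict"` (ties wrong) or `"half-credit"`.
#' @return PC in `[0, 1]`.
#' @export
percent_correct <- function(pred, exp, ties = c("strict", "half-credit")) {
  ties <- match.arg(ties)
  if (length(pred) != length(exp)) .stopf("length mismatch: %d vs %d",
                                          length(pred), length(exp))
  n <- length(pred)
  if (n < 2L) .stopf("need at least 2 values")
  de <- sign(outer(exp, exp, "-"))
  dp <- sign(outer(pred, pred, "-"))
  good <- (de == dp & de != 0)
  if (ties == "half-credit")
    score <- good + 0.5 * (de != dp & (de == 0 | dp == 0))
  else
    score <- good
  diag(score) <- 0
  mean(rowSums(score) / (n - 1L))
}

#' Full metrics report for predicted vs experimental affinities
#'
#' @inheritParams mue
#' @param ties tie convention for [percent_correct()].
#' @return Object of class `metrics_report`: list with `MUE`, `R`, `PI`,
#'   `PC`, `n`.
#' @export
metrics_report <- function(pred, exp, ties = "strict") {
  structure(list(
    MUE = mue(pred, exp),
    R = pearson_r(pred, exp),
    PI = predictive_index(pred, exp),
    PC = percent_correct(pred, exp, ties),
    n = length(pred)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  MUE=%.3f  R=%.3f  PI=%.3f  PC=%.3f\n",
              x$n, x$MUE, x$R, x$PI, x$PC))
  invisible(x)
}
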