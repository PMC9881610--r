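#' The five physicochemical descriptors of the property model
#' @keywords internal
.PPM_DESCRIPTORS <- c("logP", "logS", "TPSA", "MW", "vdw_volume")

#' Build the feature matrix for the property / consensus model
#'
#' `"ppm_only"` mode yields the five physicochemical descriptors
#' (partition coefficient logP, solubility logS, topological polar
#' surface area, molecular weight, van der Waals volume);
#' `"consensus"` appends the structure-based predicted pIC50 (from any of
#' the neutral / charged / HH-weighted LGFE variants) as a sixth
#' regressor.
#'
#' @param descriptors data.frame with a `compound` column and the five
#'   descriptor columns `logP`, `logS`, `TPSA`, `MW`, `vdw_volume`.
#' @param silcs_pic50 named numeric vector of structure-based predicted
#'   pIC50 (names = compound ids); required for consensus mode.
#' @param mode `"ppm_only"` or `"consensus"`.
#' @return Numeric matrix (rownames = compound ids) ready for
#'   [fit_mlr()].
#' @export
build_feature_matrix <- function(descriptors, silcs_pic50 = NULL,
                                 mode = c("ppm_only", "consensus")) {
  mode <- match.arg(mode)
  if (!("compound" %in% names(descriptors)))
    .stopf("descriptor table needs a 'compound' column")
  miss <- setdiff(.PPM_DESCRIPTORS, names(descriptors))
  if (length(miss) > 0L)
    .stopf("descriptor table missing column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(descriptors[, .PPM_DESCRIPTORS])
  rownames(X) <- descriptors$compound
  if (!all(is.finite(X))) .stopf("descriptors must be finite for all compounds")
  if (mode == "consensus") {
    if (is.null(silcs_pic50)) .stopf("consensus mode requires 'silcs_pic50'")
    absent <- setdiff(rownames(X), names(silcs_pic50))
    if (length(absent) > 0L)
      .stopf("no structure-based prediction for compound(s): %s",
             paste(absent, collapse = ", "))
    X <- cbind(X, silcs_pic50 = unname(silcs_pic50[rownames(X)]))
  }
  X
}

#' Fit a multiple linear regression model
#'
#' Ordinary least squares with intercept over the given feature matrix.
#' Rank-deficient designs are rejected with the offending columns named,
#' as are fits with fewer observations than parameters.
#'
#' @param X numeric feature matrix (n x p), column names required.
#' @param y numeric response (experimental pIC50).
#' @return Object of class `mlr_model`: `features`, `coefficients`,
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) .stopf("'X' must have column names")
  if (length(y) != nrow(X))
    .stopf("response length %d does not match %d rows", length(y), nrow(X))
  if (anyNA(X) || anyNA(y)) .stopf("missing values are not allowed")
  p <- ncol(X)
  if (nrow(X) <= p + 1L)
    .stopf("need more than %d observations to fit %d features + intercept",
           p + 1L, p)
  design <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    bad <- colnames(design)[qr_$pivot[(qr_$rank + 1L):ncol(design)]]
    .stopf("rank-deficient design; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(design, y)
  cf <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    features = colnames(X),
    coefficients = unname(cf[-1L]),
    intercept = unname(cf[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = nrow(X)
  ), class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d features, n=%d, R^2=%.4f\n",
              length(x$features), x$n, x$r_squared))
  cat(sprintf("  intercept %.4g; %s\n", x$intercept,
              paste(sprintf("%s=%.4g", x$features, x$coefficients),
                    collapse = ", ")))
  invisible(x)
}

#' Predict from an MLR model
#'
#' @param object an `mlr_model`.
#' @param X feature matrix with the model's columns.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlr_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!identical(colnames(X), object$features))
    .stopf("feature columns (%s) do not match the model (%s)",
           paste(colnames(X), collapse = ", "),
           paste(object$features, collapse = ", "))
  as.vector(object$intercept + X %*% object$coefficients)
}

#' Persist / load an MLR model (YAML)
#'
#' @param model an `mlr_model`.
#' @param path YAML path.
#' @export
write_mlr_model <- function(model, path) {
  yaml::write_yaml(unclass(model), path, precision = 17)
  invisible(path)
}

#' @rdname write_mlr_model
#' @export
read_mlr_model <- function(path) {
  m <- yaml::read_yaml(path)
  structure(list(features = unlist(m$features),
                 coefficients = as.numeric(unlist(m$coefficients)),
                 intercept = as.numeric(m$intercept),
                 r_squared = as.numeric(m$r_squared),
                 n = as.integer(m$n)), class = "mlr_model")
}
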