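#' Epigenetic age acceleration (AA) residuals
#'
#' Age acceleration is the part of an epigenetic clock not explained by
#' chronological age and blood-cell composition: the ordinary least-squares
#' residual of the clock value regressed on the supplied predictors
#' (typically six estimated blood-cell proportions plus chronological age).
#' Individuals with a missing clock value or any missing predictor are
#' excluded from the fit and receive a missing residual.
#'
#' @param clock_values numeric vector of raw epigenetic clock values.
#' @param predictors numeric matrix or data.frame, rows aligned with
#'   `clock_values`; columns are the regressors (an intercept is added).
#' @return list with `residuals` (same length as `clock_values`, `NA` where
#'   input was incomplete) and `model`, a `residual_model` holding the
#'   intercept, named coefficients, `n_used` and `r_squared`.
#' @examples
#' age <- seq(40, 60, length.out = 20)
#' cells <- matrix(runif(20 * 2), 20, dimnames = list(NULL, c("cd4t", "nk")))
#' clock <- 0.8 * age + rnorm(20, sd = 0.5)
#' aa <- compute_age_acceleration(clock, cbind(cells, age = age))
#' round(sum(aa$residuals), 10)
#' @export
compute_age_acceleration <- function(clock_values, predictors) {
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  }
  if (nrow(predictors) != length(clock_values)) {
    stop("predictors must have one row per clock value", call. = FALSE)
  }
  ok <- !is.na(clock_values) & stats::complete.cases(predictors)
  X <- cbind(`(Intercept)` = 1, predictors[ok, , drop = FALSE])
  y <- clock_values[ok]
  if (nrow(X) < ncol(X)) {
    stop("fewer complete observations (", nrow(X), ") than parameters (",
         ncol(X), ")", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(X %*% beta)
  res <- rep(NA_real_, length(clock_values))
  res[ok] <- y - fitted
  r2 <- if (stats::var(y) > 0) 1 - sum((y - fitted)^2) / sum((y - mean(y))^2) else NA_real_
  model <- structure(list(intercept = unname(beta[1]),
                          coefficients = beta[-1],
                          n_used = sum(ok), r_squared = r2),
                     class = "residual_model")
  list(residuals = res, model = model)
}

#' @export
print.residual_model <- function(x, ...) {
  cat(sprintf("AA residual model: n = %d, R^2 = %.4f\n", x$n_used, x$r_squared))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Standardize a metric to zero mean and unit variance
#'
#' Centers and scales using the mean and sample standard deviation (n - 1
#' denominator) of the non-missing entries; missing entries stay missing.
#' Epigenetic age metrics are standardized this way before twin modelling so
#' variance components are directly comparable across clocks.
#'
#' @param values numeric vector with at least two distinct non-missing values.
#' @return list with `values` (the z-scores) and `params`, a
#'   `standardization_params` object with `mean` and `sd`.
#' @seealso [destandardize()]
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero variance: cannot standardize a constant metric",
                   call. = FALSE)
  structure(list(values = (values - m) / s,
                 params = structure(list(mean = m, sd = s, sd_convention = "sample (n-1)"),
                                    class = "standardization_params")))
}

#' Invert a standardization
#'
#' @param values standardized numeric vector.
#' @param params `standardization_params` from [standardize()].
#' @return values on the original scale.
#' @export
destandardize <- function(values, params) {
  stopifnot(inherits(params, "standardization_params"))
  values * params$sd + params$mean
}
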