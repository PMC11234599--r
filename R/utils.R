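# Internal numerical helpers shared by the model-fitting modules.

# Large finite penalty returned when an implied covariance matrix is not
# positive definite, so gradient-based optimizers retreat instead of aborting.
.NONPD_PENALTY <- 1e10

LOG2PI <- log(2 * pi)

#' Full-information -2 log-likelihood for grouped multivariate-normal rows
#'
#' Each row of `y` is one twin pair; its covariance matrix depends only on the
#' pair's zygosity while its mean may differ row by row (covariate effects).
#' Rows with missing entries contribute the marginal density of their observed
#' coordinates; rows with nothing observed contribute zero.
#'
#' @param y numeric matrix (n x k) of observations, `NA` allowed.
#' @param means numeric matrix (n x k) of model-implied means.
#' @param zyg character vector of length n ("MZ"/"DZ").
#' @param sigma_list named list with elements `MZ` and `DZ`, each k x k.
#' @return -2 log-likelihood, or a large penalty if a required submatrix of an
#'   implied covariance is not positive definite.
#' @keywords internal
#' @noRd
neg2ll_mvn_fiml <- function(y, means, zyg, sigma_list,
                            groups = fiml_groups(y, zyg)) {
  total <- 0
  for (grp in groups) {
    keep <- grp$keep
    sig <- sigma_list[[grp$zygosity]][keep, keep, drop = FALSE]
    if (!all(is.finite(sig))) return(.NONPD_PENALTY)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch) || !all(is.finite(ch)) || any(diag(ch) < 1e-10)) {
      return(.NONPD_PENALTY)
    }
    r <- y[grp$idx, keep, drop = FALSE] - means[grp$idx, keep, drop = FALSE]
    # quadratic forms via one triangular solve for the whole group
    u <- backsolve(ch, t(r), transpose = TRUE)
    logdet <- 2 * sum(log(diag(ch)))
    total <- total +
      sum(u * u) + length(grp$idx) * (logdet + sum(keep) * LOG2PI)
  }
  if (!is.finite(total)) return(.NONPD_PENALTY)
  total
}

# Precompute (zygosity x missingness-pattern) row groups so repeated
# likelihood evaluations inside an optimizer skip the bookkeeping.
fiml_groups <- function(y, zyg) {
  obs <- !is.na(y)
  pattern <- obs %*% (2^(seq_len(ncol(y)) - 1))
  groups <- list()
  for (z in unique(zyg)) {
    for (p in unique(pattern[zyg == z])) {
      idx <- which(zyg == z & pattern == p)
      keep <- obs[idx[1L], ]
      if (!any(keep)) next
      groups[[length(groups) + 1L]] <-
        list(zygosity = z, idx = idx, keep = keep)
    }
  }
  groups
}

# Central-difference gradient used for convergence diagnostics.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Numerical Hessian of a scalar function (used for delta-method fallback CIs).
num_hess <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- numeric(n); ei[i] <- h
    ej <- numeric(n); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h * h)
  }
  H
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation of complete pairs; NA (not an error) when undefined.
safe_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf("%.*f(%.*f, %.*f)", digits, est, digits, lo, digits, hi)
}
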