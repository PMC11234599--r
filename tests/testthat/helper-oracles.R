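# Independent oracles: brute-force recomputations used to check the package's
# likelihood and regression machinery. They deliberately share no code with
# the implementation (explicit inverses and determinants, direct formulas).

# -2 log density of one multivariate-normal observation, observed entries only.
oracle_neg2ll_pair <- function(y, mean, sigma) {
  obs <- !is.na(y)
  y <- y[obs]; mean <- mean[obs]
  sigma <- sigma[obs, obs, drop = FALSE]
  d <- y - mean
  as.numeric(log(det(sigma)) + t(d) %*% solve(sigma) %*% d +
               length(y) * log(2 * pi))
}

# One-wave twin-pair covariance built straight from the sharing coefficients.
oracle_uv_sigma <- function(a2, c2, d2, e2, zygosity) {
  v <- a2 + c2 + d2 + e2
  cv <- if (zygosity == "MZ") a2 + c2 + d2 else 0.5 * a2 + c2 + 0.25 * d2
  matrix(c(v, cv, cv, v), 2)
}

oracle_neg2ll_univariate <- function(ds, a2, c2, d2, e2, mu) {
  y <- as.matrix(ds$pairs[c("y_1_w1", "y_2_w1")])
  sum(vapply(seq_len(nrow(y)), function(i) {
    oracle_neg2ll_pair(y[i, ], rep(mu, 2),
                       oracle_uv_sigma(a2, c2, d2, e2, ds$pairs$zygosity[i]))
  }, numeric(1)))
}

# Two-wave pair covariance from Cholesky path matrices, order
# (t1w1, t1w2, t2w1, t2w2).
oracle_bv_sigma <- function(A, C, E, zygosity) {
  blk <- function(M) if (is.null(M)) matrix(0, 2, 2) else M %*% t(M)
  W <- blk(A) + blk(C) + blk(E)
  rho_a <- if (zygosity == "MZ") 1 else 0.5
  X <- rho_a * blk(A) + blk(C)
  rbind(cbind(W, X), cbind(X, W))
}

oracle_neg2ll_bivariate <- function(ds, A, C, E, mu) {
  y <- as.matrix(ds$pairs[c("y_1_w1", "y_1_w2", "y_2_w1", "y_2_w2")])
  sum(vapply(seq_len(nrow(y)), function(i) {
    oracle_neg2ll_pair(y[i, ], rep(mu, 2),
                       oracle_bv_sigma(A, C, E, ds$pairs$zygosity[i]))
  }, numeric(1)))
}

# OLS via explicit normal equations.
oracle_ols_residuals <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1) %*% t(X1) %*% y
  as.vector(y - X1 %*% beta)
}

make_uv_ds <- function(y1, y2, zyg, ...) {
  df <- data.frame(pair_id = sprintf("p%03d", seq_along(y1)), zygosity = zyg,
                   y_1_w1 = y1, y_2_w1 = y2, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  twin_dataset(df)
}

make_bv_ds <- function(y, zyg) {
  df <- data.frame(pair_id = sprintf("p%03d", seq_len(nrow(y))),
                   zygosity = zyg, y_1_w1 = y[, 1], y_1_w2 = y[, 2],
                   y_2_w1 = y[, 3], y_2_w2 = y[, 4], stringsAsFactors = FALSE)
  twin_dataset(df)
}

# Absolute-tolerance comparison for stochastic estimates (expect_equal's
# tolerance is relative, which is the wrong scale for shares near 0).
expect_close <- function(object, expected, tol) {
  act <- testthat::quasi_label(rlang::enquo(object))
  testthat::expect(abs(act$val - expected) < tol,
                   sprintf("%s (%.4f) differs from %.4f by more than %.3f",
                           act$lab, act$val, expected, tol))
  invisible(act$val)
}

fake_fit <- function(components, m2ll, k) {
  structure(list(components = components, minus2lnL = m2ll, n_params = k),
            class = c("univariate_fit", "twin_fit"))
}
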