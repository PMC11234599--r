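test_that("implied four-variate moments follow the Cholesky structure", {
  # zero cross paths: no covariance between waves within a twin
  p <- cholesky_params(a = c(0.6, 0, 0.5), e = c(0.8, 0, 0.7))
  m <- expected_moments_bivariate(p, "MZ")
  expect_equal(m$cov[1, 2], 0)
  expect_equal(m$cov[3, 4], 0)

  # DZ cross-twin A block is exactly half the MZ block
  p2 <- cholesky_params(a = c(0.7, 0.3, 0.4), e = c(0.5, 0.1, 0.6))
  A <- p2$a %*% t(p2$a)
  mz <- expected_moments_bivariate(p2, "MZ")$cov
  dz <- expected_moments_bivariate(p2, "DZ")$cov
  expect_equal(mz[1:2, 3:4], A)
  expect_equal(dz[1:2, 3:4], 0.5 * A)

  # a11 = a21 = 1: within-twin cross-wave covariance 1
  p3 <- cholesky_params(a = c(1, 1, 0), e = diag(2))
  expect_equal(expected_moments_bivariate(p3, "DZ")$cov[1, 2], 1)

  expect_error(expected_moments_bivariate(p3, "XX"), "zygosity")
})

test_that("derived statistics invert the summary constructor exactly", {
  # printed-summary round trip at the published DunedinPACE values
  p <- cholesky_from_summary(0.70, 0.69, Ra = 0.99, Re = 0.36)
  d <- derive_bivariate_statistics(p)
  expect_equal(d$V1, 1, tolerance = 1e-12)
  expect_equal(d$V2, 1, tolerance = 1e-12)
  expect_equal(d$h2_baseline, 0.70, tolerance = 1e-10)
  expect_equal(d$h2_followup, 0.69, tolerance = 1e-10)
  expect_equal(d$Ra, 0.99, tolerance = 1e-10)
  expect_equal(d$Re, 0.36, tolerance = 1e-10)

  # with a common-environment block the proportions still close to 1
  pc <- cholesky_from_summary(0.5, 0.45, Ra = 0.8, Re = 0.3,
                              c2_baseline = 0.2, c2_followup = 0.25, Rc = 0.6)
  dc <- derive_bivariate_statistics(pc)
  expect_equal(dc$Pa + dc$Pc + dc$Pe, 1, tolerance = 1e-10)
  expect_equal(dc$Rc, 0.6, tolerance = 1e-10)

  # standardized identity: Rph = Ra*sqrt(h1 h2) + Rc*sqrt(c1 c2) + Re*sqrt(e1 e2)
  expect_equal(dc$Rph,
               0.8 * sqrt(0.5 * 0.45) + 0.6 * sqrt(0.2 * 0.25) +
                 0.3 * sqrt(0.3 * 0.3),
               tolerance = 1e-10)

  # degenerate conventions
  p0 <- cholesky_params(a = c(0.6, 0, 0.5), e = c(0.8, 0.1, 0.6))
  d0 <- derive_bivariate_statistics(p0)
  expect_equal(d0$Ra, 0)
  expect_equal(d0$Pa, 0)
  # implied CTCT ordering whenever the A cross-covariance is nonnegative
  expect_gte(d0$ctct_implied[["MZ"]], d0$ctct_implied[["DZ"]])

  expect_equal(cholesky_from_summary(0.5, 0.5, Ra = 1, Re = 0.2)$a[2, 2], 0)
  expect_error(cholesky_from_summary(0.5, 0.5, Ra = 1.2, Re = 0), "correlation")
  expect_error(cholesky_from_summary(0.8, 0.5, Ra = 0.5, Re = 0,
                                     c2_baseline = 0.3), "remainder")
})

test_that("the bivariate likelihood at the optimum matches the oracle", {
  p <- cholesky_from_summary(0.6, 0.55, Ra = 0.8, Re = 0.3)
  ds <- simulate_bivariate_twins(15, 15, p, seed = 81)
  ds$pairs$y_2_w2[3] <- NA          # FIML marginal for a missing entry
  ds$pairs$y_1_w1[7] <- NA
  fit <- fit_bivariate(ds, "AE", n_starts = 2)
  y <- as.matrix(ds$pairs[c("y_1_w1", "y_1_w2", "y_2_w1", "y_2_w2")])
  mu <- rep(fit$params$mu, 2)
  m2 <- sum(vapply(seq_len(nrow(y)), function(i) {
    oracle_neg2ll_pair(y[i, ], mu,
                       oracle_bv_sigma(fit$params$a, NULL, fit$params$e,
                                       ds$pairs$zygosity[i]))
  }, numeric(1)))
  expect_equal(fit$minus2lnL, m2, tolerance = 1e-8)
})

test_that("saturated two-wave fit equals group moments and flags singularity", {
  p <- cholesky_from_summary(0.6, 0.55, Ra = 0.8, Re = 0.3)
  ds <- simulate_bivariate_twins(40, 30, p, seed = 82)
  sat <- fit_saturated_bivariate(ds)
  y <- as.matrix(ds$pairs[c("y_1_w1", "y_1_w2", "y_2_w1", "y_2_w2")])
  for (z in c("MZ", "DZ")) {
    yz <- y[ds$pairs$zygosity == z, ]
    expect_equal(sat$group_stats[[z]]$mean, colMeans(yz), tolerance = 1e-10)
    ctr <- sweep(yz, 2, colMeans(yz))
    expect_equal(sat$group_stats[[z]]$cov, crossprod(ctr) / nrow(yz),
                 tolerance = 1e-10)
  }
  cho <- fit_bivariate(ds, "ACE", n_starts = 2)
  expect_lte(sat$minus2lnL, cho$minus2lnL + 1e-6)

  # perfectly repeated waves: the 4x4 sample covariance is singular
  ds2 <- ds
  ds2$pairs$y_1_w2 <- ds2$pairs$y_1_w1
  ds2$pairs$y_2_w2 <- ds2$pairs$y_2_w1
  expect_error(fit_saturated_bivariate(ds2), "non-positive-definite")
})

test_that("bivariate fits recover structure and respect twin exchangeability", {
  p <- cholesky_from_summary(0.65, 0.6, Ra = 0.85, Re = 0.4)
  ds <- simulate_bivariate_twins(1000, 1000, p, seed = 83)
  fit <- fit_bivariate(ds, "AE")
  expect_close(fit$derived$Ra, 0.85, 0.05)
  expect_close(fit$derived$Re, 0.40, 0.06)
  expect_close(fit$derived$h2_baseline, 0.65, 0.06)
  expect_close(fit$derived$h2_followup, 0.60, 0.06)
  expect_true(fit$converged)

  fsw <- fit_bivariate(swap_twin_order(ds), "AE")
  expect_equal(fsw$minus2lnL, fit$minus2lnL, tolerance = 1e-6)

  # null cross-wave structure: transmission paths collapse to 0
  p0 <- cholesky_params(a = c(0.7, 0, 0.6), e = c(0.7, 0, 0.7))
  ds0 <- simulate_bivariate_twins(800, 800, p0, seed = 84)
  f0 <- fit_bivariate(ds0, "AE")
  expect_lt(abs(f0$params$a[2, 1]), 0.08)
  expect_lt(abs(f0$params$e[2, 1]), 0.08)
  expect_lt(abs(f0$derived$Rph), 0.06)
})

test_that("mean bias of bivariate recoveries is small across replicates", {
  p <- cholesky_from_summary(0.7, 0.65, Ra = 0.9, Re = 0.35)
  stats <- vapply(1:10, function(i) {
    ds <- simulate_bivariate_twins(2000, 2000, p, seed = 6000 + i)
    f <- fit_bivariate(ds, "AE", n_starts = 1)
    c(f$derived$Ra, f$derived$Re, f$derived$h2_baseline, f$derived$h2_followup)
  }, numeric(4))
  bias <- rowMeans(stats) - c(0.9, 0.35, 0.7, 0.65)
  expect_lt(max(abs(bias)), 0.02)
})

test_that("observed CTCT uses symmetric double entry", {
  # co-twin's follow-up identical to twin's baseline: r = 1
  set.seed(12)
  b <- rnorm(10)
  y <- cbind(b, rnorm(10), rnorm(10), b)     # t1w1 == t2w2
  y[, 2] <- y[, 3]                           # t1w2 == t2w1 for symmetry
  ds <- make_bv_ds(y, rep("MZ", 10))
  ct <- ctct_observed(ds, "MZ")
  expect_equal(ct$r, 1, tolerance = 1e-12)
  expect_equal(ct$n_pairs, 10L)

  # relabeling twins leaves the double-entered correlation unchanged
  p <- cholesky_from_summary(0.6, 0.6, Ra = 0.9, Re = 0.3)
  ds2 <- simulate_bivariate_twins(60, 40, p, seed = 85)
  ct1 <- ctct_observed(ds2, "MZ")
  ct2 <- ctct_observed(swap_twin_order(ds2), "MZ")
  expect_equal(ct1$r, ct2$r, tolerance = 1e-12)
  expect_true(ct1$ci[1] <= ct1$r && ct1$r <= ct1$ci[2])

  # independent waves and twins: r ~ 0
  pe <- cholesky_params(e = c(1, 0, 1))
  ds3 <- simulate_bivariate_twins(4000, 0, pe, seed = 86)
  expect_lt(abs(ctct_observed(ds3, "MZ")$r), 0.04)

  expect_error(ctct_observed(make_bv_ds(matrix(rnorm(8), 2), rep("MZ", 2)),
                             "MZ"), "at least 3")
})

test_that("bivariate model selection uses the four-variate saturated reference", {
  p <- cholesky_from_summary(0.6, 0.6, Ra = 0.9, Re = 0.3)
  ds <- simulate_bivariate_twins(700, 700, p, seed = 87)
  sel <- select_model(ds)
  expect_equal(attr(sel, "selected"), "AE")
  expect_equal(sum(sel$selected), 1L)
})

test_that("profile intervals for cross-time correlations cover the truth", {
  p <- cholesky_from_summary(0.65, 0.6, Ra = 0.85, Re = 0.4)
  ds <- simulate_bivariate_twins(500, 500, p, seed = 88)
  fit <- fit_bivariate(ds, "AE")
  ci <- profile_ci(fit, "Ra")
  expect_equal(ci$method, "profile")
  expect_true(ci$lower < fit$derived$Ra && fit$derived$Ra < ci$upper)
  expect_true(ci$lower >= -1 && ci$upper <= 1)
  ci_re <- profile_ci(fit, "Re")
  expect_true(ci_re$lower < fit$derived$Re && fit$derived$Re < ci_re$upper)
  expect_error(profile_ci(fit, "Rc"), "not in the fitted")
})
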