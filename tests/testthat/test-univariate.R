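test_that("implied moments follow the twin sharing coefficients", {
  cases <- list(
    list(p = univariate_params(a = sqrt(0.5), c = sqrt(0.2), e = sqrt(0.3)),
         mz = 0.7, dz = 0.45, v = 1),
    list(p = univariate_params(a = sqrt(0.4), d = sqrt(0.2), e = sqrt(0.4)),
         mz = 0.6, dz = 0.25, v = 1),
    list(p = univariate_params(e = 1), mz = 0, dz = 0, v = 1))
  for (cs in cases) {
    mz <- expected_moments_univariate(cs$p, "MZ")
    dz <- expected_moments_univariate(cs$p, "DZ")
    expect_equal(mz$cov, matrix(c(cs$v, cs$mz, cs$mz, cs$v), 2))
    expect_equal(dz$cov[1, 2], cs$dz)
    expect_equal(mz$mean, c(0, 0))
  }
  expect_error(expected_moments_univariate(cases[[1]]$p, "OS"), "zygosity")
  # covariates shift the means per twin
  p <- univariate_params(a = 0.7, e = 0.7, mu = 1, beta = c(sex = 2))
  m <- expected_moments_univariate(p, "MZ", covariates = cbind(sex = c(0, 1)))
  expect_equal(m$mean, c(1, 3))
})

test_that("the pair likelihood matches closed forms and a brute-force oracle", {
  # one MZ pair at the origin under a pure-E standard normal model
  ds1 <- make_uv_ds(0, 0, "MZ")
  p1 <- univariate_params(e = 1)
  expect_equal(neg2_loglik_univariate(p1, ds1), 2 * log(2 * pi),
               tolerance = 1e-10)

  # 10-pair fixture with one missing co-twin: explicit inverse/determinant oracle
  set.seed(11)
  ds <- make_uv_ds(rnorm(10), rnorm(10), rep(c("MZ", "DZ"), 5))
  ds$pairs$y_2_w1[4] <- NA
  p <- univariate_params(a = 0.6, c = 0.3, e = 0.74, mu = 0.1)
  expect_equal(neg2_loglik_univariate(p, ds),
               oracle_neg2ll_univariate(ds, 0.36, 0.09, 0, 0.74^2, 0.1),
               tolerance = 1e-10)

  # exchangeable model: swapping twins leaves the likelihood unchanged
  expect_equal(neg2_loglik_univariate(p, swap_twin_order(ds)),
               neg2_loglik_univariate(p, ds), tolerance = 1e-12)
})

test_that("saturated fit recovers closed-form group moments and bounds submodels", {
  ds <- simulate_univariate_twins(60, 40, a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 21)
  sat <- fit_saturated_univariate(ds)
  y <- as.matrix(ds$pairs[c("y_1_w1", "y_2_w1")])
  for (z in c("MZ", "DZ")) {
    yz <- y[ds$pairs$zygosity == z, ]
    expect_equal(sat$group_stats[[z]]$mean, colMeans(yz), tolerance = 1e-10)
    ctr <- sweep(yz, 2, colMeans(yz))
    expect_equal(sat$group_stats[[z]]$cov, crossprod(ctr) / nrow(yz),
                 tolerance = 1e-10)
  }
  fits <- list(fit_univariate(ds, "ACE", compute_ci = FALSE),
               fit_univariate(ds, "AE", compute_ci = FALSE),
               fit_univariate(ds, "CE", compute_ci = FALSE),
               fit_univariate(ds, "E", compute_ci = FALSE))
  # nesting: -2lnL(sat) <= ACE <= AE/CE <= E
  expect_lte(sat$minus2lnL, fits[[1]]$minus2lnL + 1e-6)
  expect_lte(fits[[1]]$minus2lnL, fits[[2]]$minus2lnL + 1e-6)
  expect_lte(fits[[1]]$minus2lnL, fits[[3]]$minus2lnL + 1e-6)
  expect_lte(fits[[2]]$minus2lnL, fits[[4]]$minus2lnL + 1e-6)
  expect_lte(fits[[3]]$minus2lnL, fits[[4]]$minus2lnL + 1e-6)
  # standardized components always sum to 1; AIC identity
  for (f in fits) {
    expect_equal(sum(f$standardized), 1, tolerance = 1e-6)
    expect_equal(f$aic, f$minus2lnL + 2 * f$n_params)
  }
  expect_error(fit_saturated_univariate(make_uv_ds(rep(1, 4), rep(1, 4),
                                                   rep(c("MZ", "DZ"), 2))),
               "zero variance")
})

test_that("likelihood-ratio tests respect the model lattice", {
  g <- fake_fit("ACE", 100, 5)
  n <- fake_fit("AE", 100, 4)
  lrt <- likelihood_ratio_test(g, n)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value, 1)

  lrt <- likelihood_ratio_test(g, fake_fit("AE", 103.841, 4))
  expect_equal(lrt$p_value, 0.05, tolerance = 1e-3)

  expect_error(likelihood_ratio_test(fake_fit("ADE", 99, 5),
                                     fake_fit("CE", 100, 4)),
               "not nested")
  expect_error(likelihood_ratio_test(n, g), "fewer parameters")
})

test_that("ML estimates match a dense grid search on a small fixture", {
  ds <- simulate_univariate_twins(18, 12, a2 = 0.6, e2 = 0.4, seed = 31)
  fit <- fit_univariate(ds, "AE", compute_ci = FALSE)
  mu <- fit$mu
  grid_a <- seq(0.05, 1.4, by = 0.01)
  grid_e <- seq(0.05, 1.4, by = 0.01)
  gmin <- Inf; garg <- c(NA, NA)
  for (a in grid_a) for (e in grid_e) {
    v <- oracle_neg2ll_univariate(ds, a^2, 0, 0, e^2, mu)
    if (v < gmin) { gmin <- v; garg <- c(a, e) }
  }
  expect_lte(fit$minus2lnL, gmin + 1e-6)
  expect_close(unname(fit$paths[["a"]]), garg[1], 0.011)
  expect_close(unname(fit$paths[["e"]]), garg[2], 0.011)
})

test_that("fits recover generating parameters and are order-invariant", {
  ds <- simulate_univariate_twins(2000, 2000, a2 = 0.45, e2 = 0.55, seed = 41)
  fit <- fit_univariate(ds, "AE", compute_ci = FALSE)
  expect_close(fit$h2, 0.45, 0.05)
  expect_true(fit$converged)

  # Falconer consistency: h2 ~ 2(rMZ - rDZ)
  s <- twin_summary(ds)
  expect_close(fit$h2 - 2 * (s$r[s$zygosity == "MZ"] - s$r[s$zygosity == "DZ"]),
               0, 0.05)

  # no familial resemblance: h2 ~ 0, e2 share ~ 1
  ds0 <- simulate_univariate_twins(800, 800, e2 = 1, seed = 42)
  f0 <- fit_univariate(ds0, "AE", compute_ci = FALSE)
  expect_lt(f0$h2, 0.06)
  expect_gt(f0$e2_share, 0.94)

  # ACE on AE-generated data: shared environment collapses to ~0
  face <- fit_univariate(ds, "ACE", compute_ci = FALSE)
  expect_lt(face$standardized[["c2"]], 0.05)

  # within-pair twin swaps leave the fit unchanged
  fsw <- fit_univariate(swap_twin_order(ds), "AE", compute_ci = FALSE)
  expect_equal(fsw$minus2lnL, fit$minus2lnL, tolerance = 1e-6)
  expect_equal(fsw$h2, fit$h2, tolerance = 1e-5)
})

test_that("mean bias of h2 under the true model is small across replicates", {
  est <- vapply(1:20, function(i) {
    ds <- simulate_univariate_twins(2000, 2000, a2 = 0.45, e2 = 0.55,
                                    seed = 5000 + i)
    fit_univariate(ds, "AE", compute_ci = FALSE, n_starts = 1)$h2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.45), 0.01)
})

test_that("covariate effects are absorbed by the means model", {
  ds <- simulate_univariate_twins(800, 800, a2 = 0.5, e2 = 0.5, seed = 51,
                                  sex_p = 0.5, beta = c(sex = 1.5))
  fit <- fit_univariate(ds, "AE", covariates = "sex", compute_ci = FALSE)
  expect_close(unname(fit$beta[["sex"]]), 1.5, 0.1)
  expect_close(fit$h2, 0.5, 0.06)
  # ignoring the covariate inflates the apparent shared variance
  expect_gt(fit_univariate(ds, "ACE", compute_ci = FALSE)$standardized[["c2"]],
            0.05)
})

test_that("model selection finds the generating family", {
  ds <- simulate_univariate_twins(1500, 1500, a2 = 0.5, e2 = 0.5, seed = 61)
  sel <- select_model(ds)
  expect_equal(attr(sel, "selected"), "AE")
  expect_equal(sum(sel$selected), 1L)
  expect_true(all(sel$lrt_stat >= -1e-6, na.rm = TRUE))
  # comparison table mirrors the published layout: every candidate with
  # its LRT against a named reference and an AIC
  expect_true(all(c("model", "minus2lnL", "n_params", "ref", "lrt_stat",
                    "df", "p_value", "aic", "selected") %in% names(sel)))
  expect_setequal(sel$model, c("saturated", "ACE", "ADE", "AE", "CE", "E"))
})

test_that("profile intervals behave like likelihood intervals", {
  # boundary clip: E-only data has h2 lower bound 0
  ds0 <- simulate_univariate_twins(300, 300, e2 = 1, seed = 71)
  f0 <- fit_univariate(ds0, "AE")
  expect_equal(f0$h2_ci[1], 0)

  # interval width shrinks with n
  ds_small <- simulate_univariate_twins(250, 250, a2 = 0.5, e2 = 0.5, seed = 72)
  ds_big <- simulate_univariate_twins(2500, 2500, a2 = 0.5, e2 = 0.5, seed = 73)
  w_small <- diff(fit_univariate(ds_small, "AE")$h2_ci)
  w_big <- diff(fit_univariate(ds_big, "AE")$h2_ci)
  expect_lt(w_big, w_small)

  # near-quadratic likelihood: profile and delta agree within 10%
  fit <- fit_univariate(ds_big, "AE", compute_ci = FALSE)
  prof <- profile_ci(fit, "h2")
  delta <- twinace:::.uv_delta_ci(fit, "h2", 0.95)
  expect_equal(prof$lower, delta$lower, tolerance = 0.1)
  expect_equal(prof$upper, delta$upper, tolerance = 0.1)
})
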