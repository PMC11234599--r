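#' @title Synthetic twin-pair generators
#'
#' @description
#' Generators draw twin pairs directly from the model-implied multivariate
#' normal for each zygosity (MZ sharing coefficients 1 for A and D, DZ 0.5
#' for A and 0.25 for D, C fully shared, E unshared), which is exactly
#' equivalent in distribution to simulating the latent components and
#' simpler to verify against the closed-form moments. A latent-draw mode is
#' available for didactic traces. Same-sex adult pairs are emulated: the
#' optional sex and age covariates are shared within a pair.
#'
#' @name synthetic-twins
NULL

.draw_pairs <- function(n, mean, sigma) {
  if (n == 0L) return(matrix(numeric(0), 0, length(mean)))
  z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(z %*% chol(sigma), 2, mean, `+`)
}

# Latent-component draw with cross-twin correlation rho per component.
.draw_latent <- function(n, L, rho) {
  p <- ncol(L)
  shared <- matrix(stats::rnorm(n * p), n)
  u1 <- matrix(stats::rnorm(n * p), n)
  u2 <- matrix(stats::rnorm(n * p), n)
  z1 <- sqrt(rho) * shared + sqrt(1 - rho) * u1
  z2 <- sqrt(rho) * shared + sqrt(1 - rho) * u2
  list(t1 = z1 %*% t(L), t2 = z2 %*% t(L))
}

.sim_covariates <- function(n, sex_p, age_range, n_waves, age_gap = 5) {
  out <- list()
  if (!is.null(sex_p)) {
    out$sex <- stats::rbinom(n, 1, sex_p)        # shared: same-sex pairs
  }
  if (!is.null(age_range)) {
    age <- stats::runif(n, age_range[1], age_range[2])  # twins share age
    if (n_waves == 2L) {
      out$age_w1 <- age
      out$age_w2 <- age + age_gap
    } else {
      out$age <- age
    }
  }
  out
}

.attach_covariates <- function(pairs, covs, n_waves) {
  for (nm in names(covs)) {
    if (grepl("_w[0-9]+$", nm)) {
      base <- sub("_w([0-9]+)$", "", nm)
      w <- sub("^.*_w", "", nm)
      pairs[[sprintf("%s_1_w%s", base, w)]] <- covs[[nm]]
      pairs[[sprintf("%s_2_w%s", base, w)]] <- covs[[nm]]
    } else {
      pairs[[paste0(nm, "_1")]] <- covs[[nm]]
      pairs[[paste0(nm, "_2")]] <- covs[[nm]]
    }
  }
  pairs
}

#' Simulate one-wave twin pairs
#'
#' Draws each pair's phenotype 2-vector from the exact model-implied
#' mean and covariance for its zygosity ([expected_moments_univariate()]).
#' Deterministic given `seed`; the global RNG state is left untouched.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param a2,c2,d2,e2 generating variance components (`e2 > 0`; `c2` and
#'   `d2` not both positive).
#' @param mu grand mean.
#' @param beta named covariate effects on the mean (covariates must be
#'   generated, see `sex_p`/`age_range`); default none.
#' @param sex_p if non-`NULL`, generate a pair-shared sex covariate
#'   ~ Bernoulli(`sex_p`) coded 0/1.
#' @param age_range if non-`NULL`, generate a pair-shared age covariate
#'   ~ Uniform(range) in years.
#' @param seed integer seed (required: generation is a reproducible design
#'   choice, not an afterthought).
#' @param method `"mvn"` draws the implied bivariate normal directly;
#'   `"latent"` draws the latent A/C/D/E components per twin.
#' @param variable_name phenotype label.
#' @return a one-wave [twin_dataset()].
#' @examples
#' ds <- simulate_univariate_twins(100, 100, a2 = 0.5, c2 = 0.2, e2 = 0.3,
#'                                 seed = 1)
#' twin_summary(ds)
#' @export
simulate_univariate_twins <- function(n_mz, n_dz, a2 = 0, c2 = 0, d2 = 0, e2,
                                      mu = 0, beta = NULL, sex_p = NULL,
                                      age_range = NULL, seed,
                                      method = c("mvn", "latent"),
                                      variable_name = "y") {
  method <- match.arg(method)
  stopifnot(a2 >= 0, c2 >= 0, d2 >= 0, e2 > 0)
  if (c2 > 0 && d2 > 0) stop("c2 and d2 cannot both be positive", call. = FALSE)
  if (n_mz + n_dz == 0L) stop("at least one pair must be requested", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducible simulation", call. = FALSE)
  params <- univariate_params(a = sqrt(a2), c = sqrt(c2), d = sqrt(d2),
                              e = sqrt(e2), mu = mu, beta = beta)
  withr::with_seed(seed, {
    n <- n_mz + n_dz
    zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
    covs <- .sim_covariates(n, sex_p, age_range, n_waves = 1L)
    y <- matrix(NA_real_, n, 2)
    for (z in c("MZ", "DZ")) {
      sel <- zyg == z
      if (!any(sel)) next
      if (method == "mvn") {
        mom <- expected_moments_univariate(params, z)
        y[sel, ] <- .draw_pairs(sum(sel), mom$mean, mom$cov)
      } else {
        nz <- sum(sel)
        rho <- switch(z, MZ = c(1, 1, 1, 0), DZ = c(0.5, 1, 0.25, 0))
        acc <- matrix(mu, nz, 2)
        L <- c(sqrt(a2), sqrt(c2), sqrt(d2), sqrt(e2))
        for (i in 1:4) {
          if (L[i] == 0) next
          d <- .draw_latent(nz, matrix(L[i], 1, 1), rho[i])
          acc <- acc + cbind(d$t1, d$t2)
        }
        y[sel, ] <- acc
      }
    }
    if (!is.null(beta)) {
      for (nm in names(beta)) {
        if (!nm %in% names(covs)) {
          stop("covariate effect '", nm, "' has no generator", call. = FALSE)
        }
        y <- y + beta[[nm]] * covs[[nm]]
      }
    }
    pairs <- data.frame(pair_id = sprintf("p%05d", seq_len(n)), zygosity = zyg,
                        y_1_w1 = y[, 1], y_2_w1 = y[, 2],
                        stringsAsFactors = FALSE)
    pairs <- .attach_covariates(pairs, covs, n_waves = 1L)
    twin_dataset(pairs, variable_name = variable_name)
  })
}

#' Simulate two-wave twin pairs from Cholesky parameters
#'
#' Each pair's 4-vector (twin1-wave1, twin1-wave2, twin2-wave1, twin2-wave2)
#' is drawn from the exact model-implied moments for its zygosity
#' ([expected_moments_bivariate()]). Deterministic given `seed`.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param params generating truth, a [cholesky_params()] object (e.g. from
#'   [cholesky_from_summary()]).
#' @inheritParams simulate_univariate_twins
#' @return a two-wave [twin_dataset()].
#' @export
simulate_bivariate_twins <- function(n_mz, n_dz, params, sex_p = NULL,
                                     age_range = NULL, seed,
                                     method = c("mvn", "latent"),
                                     variable_name = "y") {
  method <- match.arg(method)
  stopifnot(inherits(params, "cholesky_params"))
  if (n_mz + n_dz == 0L) stop("at least one pair must be requested", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducible simulation", call. = FALSE)
  withr::with_seed(seed, {
    n <- n_mz + n_dz
    zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
    covs <- .sim_covariates(n, sex_p, age_range, n_waves = 2L)
    y <- matrix(NA_real_, n, 4)
    for (z in c("MZ", "DZ")) {
      sel <- zyg == z
      if (!any(sel)) next
      if (method == "mvn") {
        mom <- expected_moments_bivariate(params, z)
        y[sel, ] <- .draw_pairs(sum(sel), mom$mean, mom$cov)
      } else {
        nz <- sum(sel)
        rho <- switch(z, MZ = c(a = 1, c = 1, d = 1, e = 0),
                      DZ = c(a = 0.5, c = 1, d = 0.25, e = 0))
        acc <- matrix(rep(params$mu, 2), nz, 4, byrow = TRUE)
        for (k in names(.bv_components(params))) {
          d <- .draw_latent(nz, params[[k]], rho[[k]])
          acc <- acc + cbind(d$t1, d$t2)
        }
        y[sel, ] <- acc
      }
    }
    if (!is.null(params$beta)) {
      for (nm in names(params$beta)) {
        val <- covs[[nm]]
        if (is.null(val)) {
          w1 <- covs[[paste0(nm, "_w1")]]; w2 <- covs[[paste0(nm, "_w2")]]
          if (is.null(w1)) stop("covariate effect '", nm, "' has no generator",
                                call. = FALSE)
          y <- y + params$beta[[nm]] * cbind(w1, w2, w1, w2)
        } else {
          y <- y + params$beta[[nm]] * val
        }
      }
    }
    pairs <- data.frame(pair_id = sprintf("p%05d", seq_len(n)), zygosity = zyg,
                        y_1_w1 = y[, 1], y_1_w2 = y[, 2],
                        y_2_w1 = y[, 3], y_2_w2 = y[, 4],
                        stringsAsFactors = FALSE)
    pairs <- .attach_covariates(pairs, covs, n_waves = 2L)
    twin_dataset(pairs, variable_name = variable_name)
  })
}

#' Build standardized Cholesky parameters from printed summary statistics
#'
#' Inverts the published summary of a bivariate twin analysis -- per-wave
#' heritabilities, optional common-environment shares, and the cross-time
#' genetic (`Ra`), common-environment (`Rc`) and unique-environment (`Re`)
#' correlations -- into a standardized (unit variance at both waves)
#' Cholesky parameterization:
#' \deqn{a_{11} = \sqrt{h^2_1},\quad a_{21} = R_a \sqrt{h^2_2},\quad
#'       a_{22} = \sqrt{h^2_2 (1 - R_a^2)}}
#' and analogously for the C and E paths with their shares. The E share at
#' each wave is the remainder `1 - h2 - c2`.
#' [derive_bivariate_statistics()] on the result reproduces all inputs.
#'
#' @param h2_baseline,h2_followup heritability at each wave, in [0, 1].
#' @param Ra,Re cross-time genetic and unique-environmental correlations.
#' @param c2_baseline,c2_followup common-environment shares (default 0).
#' @param Rc cross-time common-environment correlation (needed only when C
#'   shares are positive).
#' @return a [cholesky_params()] object with V1 = V2 = 1.
#' @examples
#' p <- cholesky_from_summary(0.70, 0.69, Ra = 0.99, Re = 0.36)
#' derive_bivariate_statistics(p)
#' @export
cholesky_from_summary <- function(h2_baseline, h2_followup, Ra, Re,
                                  c2_baseline = 0, c2_followup = 0, Rc = 0) {
  shares1 <- c(h2_baseline, c2_baseline)
  shares2 <- c(h2_followup, c2_followup)
  if (any(c(shares1, shares2) < 0) || any(c(shares1, shares2) > 1)) {
    stop("variance shares must lie in [0, 1]", call. = FALSE)
  }
  for (r in c(Ra, Re, Rc)) {
    if (abs(r) > 1) stop("|correlation| must not exceed 1", call. = FALSE)
  }
  e2_1 <- 1 - sum(shares1)
  e2_2 <- 1 - sum(shares2)
  if (e2_1 < -1e-12 || e2_2 < -1e-12) {
    stop("shares exceed 1: the unique-environment remainder is negative",
         call. = FALSE)
  }
  e2_1 <- max(e2_1, 0); e2_2 <- max(e2_2, 0)
  path3 <- function(s1, s2, r) {
    c(sqrt(s1), r * sqrt(s2), sqrt(s2 * (1 - r^2)))
  }
  cholesky_params(
    a = path3(h2_baseline, h2_followup, Ra),
    c = if (c2_baseline > 0 || c2_followup > 0) path3(c2_baseline, c2_followup, Rc),
    e = path3(e2_1, e2_2, Re))
}
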