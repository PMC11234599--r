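#' @title Univariate twin variance-component models
#'
#' @description
#' One-wave twin models decompose the phenotypic variance into additive
#' genetic (A), common environmental (C) or dominance genetic (D), and
#' unique environmental (E) latent components. MZ pairs share all additive
#' and dominance effects; DZ pairs share on average half the additive and a
#' quarter of the dominance effects; C is shared fully by both; E is
#' unshared and also absorbs measurement error. C and D cannot be estimated
#' jointly from twins reared together, so the model families are ACE and ADE
#' with sub-models AE, CE and E.
#'
#' @name univariate-twin-models
NULL

uv_path_names <- function(components) {
  switch(components,
         ACE = c("a", "c", "e"), ADE = c("a", "d", "e"),
         AE = c("a", "e"), CE = c("c", "e"), E = "e",
         stop("unknown model family: ", components, call. = FALSE))
}

comp_letters <- function(components) {
  setdiff(strsplit(components, "")[[1]], "")
}

#' Construct univariate twin-model parameters
#'
#' Path coefficients load the latent standard-normal components on the
#' phenotype; their squares are the variance components. Absent components
#' are fixed at zero.
#'
#' @param a,c,d,e path coefficients (e must be nonzero: E carries
#'   measurement error).
#' @param mu grand mean.
#' @param beta named numeric vector of covariate coefficients on the mean.
#' @return object of class `univariate_params`.
#' @export
univariate_params <- function(a = 0, c = 0, d = 0, e, mu = 0, beta = NULL) {
  if (c != 0 && d != 0) {
    stop("C and D cannot both be present: the twin design cannot identify both",
         call. = FALSE)
  }
  structure(list(a = a, c = c, d = d, e = e, mu = mu, beta = beta),
            class = "univariate_params")
}

.uv_sigma_list <- function(a2, c2, d2, e2) {
  v <- a2 + c2 + d2 + e2
  list(MZ = matrix(c(v, a2 + c2 + d2, a2 + c2 + d2, v), 2),
       DZ = matrix(c(v, 0.5 * a2 + c2 + 0.25 * d2,
                     0.5 * a2 + c2 + 0.25 * d2, v), 2))
}

#' Model-implied moments of a twin pair (one wave)
#'
#' The phenotypic variance is \eqn{a^2+c^2+d^2+e^2}; the within-pair
#' covariance is \eqn{a^2+c^2+d^2} for MZ pairs and
#' \eqn{0.5a^2+c^2+0.25d^2} for DZ pairs. Means are
#' \eqn{\mu + X\beta} per twin.
#'
#' @param params a [univariate_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param covariates optional 2 x p matrix (rows = twins, columns named as
#'   `params$beta`).
#' @return list with `mean` (length 2) and `cov` (2 x 2 matrix).
#' @export
expected_moments_univariate <- function(params, zygosity, covariates = NULL) {
  if (!zygosity %in% c("MZ", "DZ")) {
    stop("unknown zygosity: ", zygosity, call. = FALSE)
  }
  sig <- .uv_sigma_list(params$a^2, params$c^2, params$d^2, params$e^2)[[zygosity]]
  mn <- rep(params$mu, 2)
  if (!is.null(covariates) && length(params$beta)) {
    covariates <- as.matrix(covariates)
    mn <- mn + as.vector(covariates[, names(params$beta), drop = FALSE] %*%
                           params$beta)
  }
  list(mean = mn, cov = sig)
}

# Shared objective builder: theta = (paths, mu, beta...).
.uv_objective <- function(ds, components, covariates) {
  y <- pheno_matrix(ds)
  zyg <- ds$pairs$zygosity
  design <- covariate_design(ds, covariates)
  for (j in seq_along(design)) {
    if (any(!is.na(y) & is.na(design[[j]]))) {
      stop("covariate '", covariates[j],
           "' is missing for twins with observed phenotype", call. = FALSE)
    }
  }
  pn <- uv_path_names(components)
  np <- length(pn)
  n <- nrow(y)
  groups <- fiml_groups(y, zyg)
  function(theta) {
    p <- stats::setNames(rep(0, 4), c("a", "c", "d", "e"))
    p[pn] <- theta[seq_len(np)]
    mu <- theta[np + 1L]
    means <- matrix(mu, n, 2)
    for (j in seq_along(design)) {
      means <- means + theta[np + 1L + j] * design[[j]]
    }
    sig <- .uv_sigma_list(p[["a"]]^2, p[["c"]]^2, p[["d"]]^2, p[["e"]]^2)
    neg2ll_mvn_fiml(y, means, zyg, sig, groups)
  }
}

#' -2 log-likelihood of a univariate twin model
#'
#' Sum over pairs of -2 times the log bivariate-normal density with the
#' model-implied moments; pairs with one missing twin contribute the marginal
#' univariate density (full-information maximum likelihood). A
#' non-positive-definite implied covariance yields a large finite penalty so
#' optimizers retreat rather than abort.
#'
#' @param params a [univariate_params()] object.
#' @param ds a one-wave `twin_dataset`; covariates named in `params$beta`
#'   must be present.
#' @return -2 log-likelihood (scalar).
#' @export
neg2_loglik_univariate <- function(params, ds) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves != 1L) stop("univariate likelihood needs one-wave data", call. = FALSE)
  covs <- names(params$beta)
  y <- pheno_matrix(ds)
  zyg <- ds$pairs$zygosity
  design <- covariate_design(ds, covs %||% character())
  means <- matrix(params$mu, nrow(y), 2)
  for (j in seq_along(design)) means <- means + params$beta[j] * design[[j]]
  sig <- .uv_sigma_list(params$a^2, params$c^2, params$d^2, params$e^2)
  neg2ll_mvn_fiml(y, means, zyg, sig)
}

# Moment-based starting values (Falconer-style) on possibly
# covariate-adjusted residuals.
.uv_starts <- function(ds, components, covariates) {
  y <- pheno_matrix(ds)
  n <- nrow(y)
  if (length(covariates)) {
    design <- covariate_design(ds, covariates)
    yy <- c(y[, 1], y[, 2])
    X <- do.call(cbind, lapply(design, function(m) c(m[, 1], m[, 2])))
    fit <- stats::lm(yy ~ X, na.action = stats::na.exclude)
    cf <- stats::coef(fit)
    mu0 <- unname(cf[1]); beta0 <- unname(cf[-1])
    beta0[is.na(beta0)] <- 0
    res <- matrix(stats::residuals(fit), n, 2)
  } else {
    mu0 <- mean(y, na.rm = TRUE); beta0 <- numeric(0)
    res <- y - mu0
  }
  V <- stats::var(as.vector(res), na.rm = TRUE)
  mz <- ds$pairs$zygosity == "MZ"
  rmz <- safe_cor(res[mz, 1], res[mz, 2])
  rdz <- safe_cor(res[!mz, 1], res[!mz, 2])
  if (is.na(rmz)) rmz <- 0.5
  if (is.na(rdz)) rdz <- 0.25
  s <- switch(components,
    ACE = c(a = clamp(2 * (rmz - rdz), 0.05, 0.85),
            c = clamp(2 * rdz - rmz, 0.02, 0.6)),
    ADE = c(a = clamp(4 * rdz - rmz, 0.05, 0.85),
            d = clamp(2 * rmz - 4 * rdz, 0.02, 0.6)),
    AE  = c(a = clamp(rmz, 0.05, 0.9)),
    CE  = c(c = clamp(rdz, 0.05, 0.9)),
    E   = c())
  s <- c(s, e = max(0.05, 1 - sum(s)))
  s <- s / sum(s)
  paths <- sqrt(s * V)
  names(paths) <- names(s)
  list(theta = c(unname(paths[uv_path_names(components)]), mu0, beta0), V = V)
}

.optimize_multistart <- function(obj, theta0, n_starts = 5L,
                                 jitter_seed = 20240710L, jitter_sd = 0.25) {
  starts <- list(theta0)
  if (n_starts > 1L) {
    withr::with_seed(jitter_seed, {
      for (i in seq_len(n_starts - 1L)) {
        starts[[i + 1L]] <- theta0 * exp(stats::rnorm(length(theta0), 0, jitter_sd)) +
          stats::rnorm(length(theta0), 0, 0.02)
      }
    })
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  best
}

#' Fit a univariate twin model by maximum likelihood
#'
#' Maximizes the full-information pair likelihood over path coefficients and
#' the means model (grand mean plus shared covariate coefficients), using
#' BFGS from a moments-based start plus jittered restarts. Heritability is
#' \eqn{a^2/V} for the ACE family and \eqn{(a^2+d^2)/V} for the ADE family.
#' 95% confidence intervals for the standardized quantities are
#' profile-likelihood intervals (delta-method fallback, flagged via
#' `ci_method`).
#'
#' @param ds one-wave `twin_dataset` with at least one MZ and one DZ pair.
#' @param components model family: `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param covariates covariate names entering the means model.
#' @param compute_ci compute profile CIs for `h2` and the e2 share.
#' @param level confidence level.
#' @param n_starts number of optimizer starts (moments start + jittered).
#' @return object of class `univariate_fit`: paths (absolute values),
#'   variance components, standardized shares, `h2`/`e2_share` with CIs,
#'   `minus2lnL`, `n_params`, `aic`, convergence diagnostics.
#' @export
fit_univariate <- function(ds, components = c("ACE", "ADE", "AE", "CE", "E"),
                           covariates = character(), compute_ci = TRUE,
                           level = 0.95, n_starts = 5L) {
  components <- match.arg(components)
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves != 1L) stop("fit_univariate needs one-wave data", call. = FALSE)
  check_fit_ready(ds)
  y <- pheno_matrix(ds)
  if (stats::sd(y, na.rm = TRUE) == 0) {
    stop("degenerate data: phenotype has zero variance", call. = FALSE)
  }
  obj <- .uv_objective(ds, components, covariates)
  st <- .uv_starts(ds, components, covariates)
  best <- .optimize_multistart(obj, st$theta, n_starts = n_starts)
  theta <- best$par
  pn <- uv_path_names(components)
  np <- length(pn)
  paths <- stats::setNames(rep(0, 4), c("a", "c", "d", "e"))
  paths[pn] <- abs(theta[seq_len(np)])
  theta[seq_len(np)] <- paths[pn]
  grad <- num_grad(obj, theta)
  grad_norm <- sqrt(sum(grad^2))
  converged <- best$convergence == 0 &&
    grad_norm < 1e-5 * max(1, abs(best$value))
  if (!converged) {
    warning("fit_univariate(", components, "): convergence not confirmed ",
            sprintf("(optim code %d, |grad| = %.3g)", best$convergence, grad_norm),
            call. = FALSE)
  }
  vc <- paths^2
  V <- sum(vc)
  shares <- vc / V
  names(shares) <- paste0(names(vc), "2")
  h2 <- if (components %in% c("ADE")) shares[["a2"]] + shares[["d2"]] else shares[["a2"]]
  n_params <- np + 1L + length(covariates)
  fit <- structure(list(
    components = components, covariate_names = covariates,
    paths = paths[pn],
    mu = theta[np + 1L],
    beta = stats::setNames(theta[np + 1L + seq_along(covariates)], covariates),
    variance_components = vc, total_variance = V,
    standardized = shares,
    h2 = h2, e2_share = shares[["e2"]],
    minus2lnL = best$value, n_params = n_params,
    aic = best$value + 2 * n_params,
    converged = converged, grad_norm = grad_norm,
    optim_convergence = best$convergence,
    theta = theta, dataset = ds, level = level,
    ci_method = NULL, h2_ci = NULL, e2_share_ci = NULL),
    class = c("univariate_fit", "twin_fit"))
  if (compute_ci) {
    ci_h2 <- profile_ci(fit, "h2", level = level)
    ci_e2 <- profile_ci(fit, "e2_share", level = level)
    fit$h2_ci <- c(ci_h2$lower, ci_h2$upper)
    fit$e2_share_ci <- c(ci_e2$lower, ci_e2$upper)
    fit$ci_method <- unique(c(ci_h2$method, ci_e2$method))
  }
  fit
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("%s twin model: -2lnL = %.3f, AIC = %.3f (k = %d)%s\n",
              x$components, x$minus2lnL, x$aic, x$n_params,
              if (x$converged) "" else " [NOT CONVERGED]"))
  sh <- round(x$standardized, 3)
  cat("Standardized components:",
      paste(sprintf("%s = %.3f", names(sh), sh), collapse = ", "), "\n")
  if (!is.null(x$h2_ci)) {
    cat(sprintf("h2 = %s   e2 share = %s\n",
                fmt_ci(x$h2, x$h2_ci[1], x$h2_ci[2]),
                fmt_ci(x$e2_share, x$e2_share_ci[1], x$e2_share_ci[2])))
  } else {
    cat(sprintf("h2 = %.3f   e2 share = %.3f\n", x$h2, x$e2_share))
  }
  invisible(x)
}

#' Fit the fully saturated one-wave model
#'
#' Per-zygosity means and 2 x 2 covariance matrices, unconstrained across
#' twin order, with covariate coefficients shared across zygosity and twin
#' order. Its -2 log-likelihood lower-bounds every constrained twin model on
#' the same data. Without covariates or missing values the maximum-likelihood
#' solution is closed form (group sample moments with 1/n covariances).
#'
#' @param ds one-wave `twin_dataset`.
#' @param covariates covariate names for the shared means model.
#' @return object of class `saturated_fit` with per-group moments,
#'   `minus2lnL` and `n_params`.
#' @export
fit_saturated_univariate <- function(ds, covariates = character()) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves != 1L) stop("fit_saturated_univariate needs one-wave data", call. = FALSE)
  check_fit_ready(ds)
  y <- pheno_matrix(ds)
  if (stats::sd(y, na.rm = TRUE) == 0) {
    stop("degenerate data: phenotype has zero variance", call. = FALSE)
  }
  .fit_saturated(ds, covariates, k = 2L)
}

# Saturated model for k observed coordinates per pair (k = 2 or 4).
.fit_saturated <- function(ds, covariates, k) {
  y <- pheno_matrix(ds)
  zyg <- ds$pairs$zygosity
  design <- covariate_design(ds, covariates)
  ncv <- k * (k + 1L) / 2L
  n_params <- 2L * (k + ncv) + length(covariates)

  complete <- !anyNA(y)
  if (!length(covariates) && complete) {
    group_stats <- list()
    m2ll <- 0
    for (z in c("MZ", "DZ")) {
      yz <- y[zyg == z, , drop = FALSE]
      mu <- colMeans(yz)
      ctr <- sweep(yz, 2, mu)
      sig <- crossprod(ctr) / nrow(yz)           # ML (1/n) covariance
      ch <- tryCatch(chol(sig), error = function(e) NULL)
      if (is.null(ch)) {
        stop("degenerate data: singular ", z, " sample covariance ",
             "(non-positive-definite)", call. = FALSE)
      }
      m2ll <- m2ll + nrow(yz) *
        (2 * sum(log(diag(ch))) + k * LOG2PI + k)
      group_stats[[z]] <- list(mean = mu, cov = sig)
    }
    return(structure(list(group_stats = group_stats, beta = NULL,
                          minus2lnL = m2ll, n_params = n_params,
                          n_waves = ds$n_waves, k = k, converged = TRUE,
                          covariate_names = covariates, dataset = ds),
                     class = c("saturated_fit", "twin_fit")))
  }

  # General case: optimize means + log-Cholesky covariances + shared betas.
  lower_idx <- which(lower.tri(diag(k), diag = TRUE))
  diag_pos <- which(lower_idx %in% which(diag(k) == 1 &
                                           lower.tri(diag(k), diag = TRUE)))
  build_sigma <- function(v) {
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- v
    diag(L) <- exp(diag(L))
    L %*% t(L)
  }
  unpack <- function(theta) {
    i <- 0L
    take <- function(n) { out <- theta[i + seq_len(n)]; i <<- i + n; out }
    list(mu_mz = take(k), v_mz = take(ncv),
         mu_dz = take(k), v_dz = take(ncv),
         beta = take(length(covariates)))
  }
  n <- nrow(y)
  groups <- fiml_groups(y, zyg)
  objfun <- function(theta) {
    p <- unpack(theta)
    means <- matrix(0, n, k)
    means[zyg == "MZ", ] <- matrix(p$mu_mz, sum(zyg == "MZ"), k, byrow = TRUE)
    means[zyg == "DZ", ] <- matrix(p$mu_dz, sum(zyg == "DZ"), k, byrow = TRUE)
    for (j in seq_along(design)) means <- means + p$beta[j] * design[[j]]
    sig <- list(MZ = build_sigma(p$v_mz), DZ = build_sigma(p$v_dz))
    neg2ll_mvn_fiml(y, means, zyg, sig, groups)
  }
  # start at complete-case moments
  start_group <- function(z) {
    yz <- y[zyg == z, , drop = FALSE]
    cc <- stats::complete.cases(yz)
    yc <- yz[cc, , drop = FALSE]
    mu <- colMeans(yc)
    sig <- if (nrow(yc) > k) stats::cov(yc) else diag(k)
    ch <- tryCatch(t(chol(sig)), error = function(e) diag(k))
    v <- ch[lower.tri(ch, diag = TRUE)]
    L <- ch; diag(L) <- log(pmax(diag(L), 1e-4))
    list(mu = mu, v = L[lower.tri(L, diag = TRUE)])
  }
  smz <- start_group("MZ"); sdz <- start_group("DZ")
  theta0 <- c(smz$mu, smz$v, sdz$mu, sdz$v, rep(0, length(covariates)))
  best <- .optimize_multistart(objfun, theta0, n_starts = 3L, jitter_sd = 0.1)
  p <- unpack(best$par)
  structure(list(group_stats = list(MZ = list(mean = p$mu_mz, cov = build_sigma(p$v_mz)),
                                    DZ = list(mean = p$mu_dz, cov = build_sigma(p$v_dz))),
                 beta = stats::setNames(p$beta, covariates),
                 minus2lnL = best$value, n_params = n_params,
                 n_waves = ds$n_waves, k = k,
                 converged = best$convergence == 0,
                 covariate_names = covariates, dataset = ds),
            class = c("saturated_fit", "twin_fit"))
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf("Saturated model (%d coordinates/pair): -2lnL = %.3f, k = %d\n",
              x$k, x$minus2lnL, x$n_params))
  invisible(x)
}

model_label <- function(fit) {
  if (inherits(fit, "saturated_fit")) "saturated" else fit$components
}

#' Likelihood-ratio test between nested twin models
#'
#' The statistic is the difference in -2 log-likelihood (floored at zero),
#' referred to a chi-square with degrees of freedom equal to the parameter
#' difference. Nesting follows the model lattice
#' E < AE/CE < ACE < saturated and E < AE < ADE < saturated.
#'
#' @param general the richer fit.
#' @param nested the constrained fit on the same data.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(general, nested) {
  if (nested$n_params >= general$n_params) {
    stop("nested model must have fewer parameters than the general model",
         call. = FALSE)
  }
  gl <- model_label(general); nl <- model_label(nested)
  if (nl == "saturated") stop("saturated model cannot be the nested model", call. = FALSE)
  if (gl != "saturated") {
    if (!all(comp_letters(nl) %in% comp_letters(gl))) {
      stop("models '", nl, "' and '", gl, "' are not nested", call. = FALSE)
    }
  }
  stat <- max(0, nested$minus2lnL - general$minus2lnL)
  df <- general$n_params - nested$n_params
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Model selection across the twin-model lattice
#'
#' Fits the saturated reference, the full ACE and ADE models, then the
#' sub-models of whichever full family has the lower AIC. A candidate is
#' admissible when its likelihood-ratio test against the full family model
#' and against the saturated model are both non-significant (`p > alpha`);
#' the full family model itself is admissible when its test against the
#' saturated model is non-significant. Among admissible candidates the
#' lowest AIC wins, ties going to the model with fewest parameters. If no
#' candidate is admissible the full family model is returned with a warning
#' flag.
#'
#' Works for one-wave data (univariate models) and two-wave data (bivariate
#' Cholesky models with the four-variate saturated reference).
#'
#' @param ds a `twin_dataset`.
#' @param covariates covariate names for the means models.
#' @param alpha significance threshold for the LRT admissibility rule.
#' @param compute_ci passed to the final univariate fits.
#' @return data.frame of class `model_comparison` (one row per fitted model:
#'   `minus2lnL`, `n_params`, LRT vs its reference, `aic`, `selected`), with
#'   attributes `fits` (named list) and `selected_fit`.
#' @export
select_model <- function(ds, covariates = character(), alpha = 0.05,
                         compute_ci = FALSE) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves == 1L) {
    fit_fun <- function(cmp) fit_univariate(ds, cmp, covariates,
                                            compute_ci = compute_ci)
    sat <- fit_saturated_univariate(ds, covariates)
  } else {
    fit_fun <- function(cmp) fit_bivariate(ds, cmp, covariates)
    sat <- fit_saturated_bivariate(ds, covariates)
  }
  fits <- list(saturated = sat)
  for (cmp in c("ACE", "ADE")) fits[[cmp]] <- fit_fun(cmp)
  family <- if (fits$ACE$aic <= fits$ADE$aic) "ACE" else "ADE"
  subs <- if (family == "ACE") c("AE", "CE", "E") else c("AE", "E")
  for (cmp in subs) fits[[cmp]] <- fit_fun(cmp)

  rows <- list()
  add_row <- function(label, fit, ref_label) {
    lrt <- if (is.na(ref_label)) list(statistic = NA_real_, df = NA_integer_,
                                      p_value = NA_real_)
           else likelihood_ratio_test(fits[[ref_label]], fit)
    rows[[length(rows) + 1L]] <<- data.frame(
      model = label, minus2lnL = fit$minus2lnL, n_params = fit$n_params,
      ref = if (is.na(ref_label)) NA_character_ else ref_label,
      lrt_stat = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
      aic = if (inherits(fit, "saturated_fit"))
        fit$minus2lnL + 2 * fit$n_params else fit$aic,
      stringsAsFactors = FALSE)
  }
  add_row("saturated", sat, NA_character_)
  add_row("ACE", fits$ACE, "saturated")
  add_row("ADE", fits$ADE, "saturated")
  for (cmp in subs) add_row(cmp, fits[[cmp]], family)
  tab <- do.call(rbind, rows)

  p_vs_sat <- function(cmp) likelihood_ratio_test(sat, fits[[cmp]])$p_value
  admissible <- character(0)
  if (p_vs_sat(family) > alpha) admissible <- family
  for (cmp in subs) {
    if (tab$p_value[tab$model == cmp] > alpha && p_vs_sat(cmp) > alpha) {
      admissible <- c(admissible, cmp)
    }
  }
  no_admissible <- length(admissible) == 0L
  if (no_admissible) {
    warning("no candidate passed the LRT admissibility rule; ",
            "keeping the full ", family, " model", call. = FALSE)
    selected <- family
  } else {
    cand <- tab[tab$model %in% admissible, ]
    cand <- cand[order(cand$aic, cand$n_params), ]
    selected <- cand$model[1]
  }
  tab$selected <- tab$model == selected
  structure(tab, class = c("model_comparison", "data.frame"),
            fits = fits, selected = selected,
            selected_fit = fits[[selected]], family = family,
            no_admissible = no_admissible)
}

#' @export
print.model_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$minus2lnL <- round(df$minus2lnL, 3)
  df$lrt_stat <- round(df$lrt_stat, 3)
  df$p_value <- signif(df$p_value, 3)
  df$aic <- round(df$aic, 3)
  print(df, row.names = FALSE)
  cat("Selected model:", attr(x, "selected"), "\n")
  invisible(x)
}

# ---- profile-likelihood confidence intervals (univariate) ----

.uv_share_value <- function(fit, quantity) {
  s <- fit$standardized
  switch(quantity,
         h2 = if (fit$components == "ADE") s[["a2"]] + s[["d2"]] else s[["a2"]],
         a2_share = s[["a2"]], c2_share = s[["c2"]],
         d2_share = s[["d2"]], e2_share = s[["e2"]])
}

# Map (q, mix t) to a full share vector for the fit's model family, or NULL
# when the quantity is structurally fixed for that family.
.uv_share_map <- function(components, quantity) {
  two <- function(first) {
    other <- setdiff(uv_path_names(components), first)
    structure(function(q, t) {
      s <- c(a = 0, c = 0, d = 0, e = 0)
      s[first] <- q; s[other] <- 1 - q
      s
    }, mix = character(0))
  }
  split2 <- function(fixed, free1, free2) {
    structure(function(q, t) {
      s <- c(a = 0, c = 0, d = 0, e = 0)
      s[fixed] <- q; s[free1] <- t * (1 - q); s[free2] <- (1 - t) * (1 - q)
      s
    }, mix = c(free1, free2))
  }
  joint2 <- function(j1, j2, rest) {   # q split across j1+j2
    structure(function(q, t) {
      s <- c(a = 0, c = 0, d = 0, e = 0)
      s[j1] <- t * q; s[j2] <- (1 - t) * q; s[rest] <- 1 - q
      s
    }, mix = c(j1, j2))
  }
  switch(components,
    AE = switch(quantity, h2 = , a2_share = two("a"), e2_share = two("e"), NULL),
    CE = switch(quantity, c2_share = two("c"), e2_share = two("e"), NULL),
    E  = NULL,
    ACE = switch(quantity,
                 h2 = , a2_share = split2("a", "c", "e"),
                 c2_share = split2("c", "a", "e"),
                 e2_share = split2("e", "a", "c"), NULL),
    ADE = switch(quantity,
                 h2 = joint2("a", "d", "e"),
                 a2_share = split2("a", "d", "e"),
                 d2_share = split2("d", "a", "e"),
                 e2_share = split2("e", "a", "d"), NULL))
}

#' Profile-likelihood confidence interval for a standardized quantity
#'
#' The bound is where the profiled -2 log-likelihood rises by the chi-square
#' quantile (3.841 at 95%) above its minimum; bounds are clipped to [0, 1].
#' When profiling fails numerically a delta-method interval is returned and
#' flagged in `method`.
#'
#' @param fit a converged `univariate_fit`.
#' @param quantity one of `"h2"`, `"a2_share"`, `"c2_share"`, `"d2_share"`,
#'   `"e2_share"`.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return list with `lower`, `upper`, `method` (`"profile"` or `"delta"`).
#' @export
profile_ci <- function(fit, quantity, level = 0.95, ...) UseMethod("profile_ci")

#' @rdname profile_ci
#' @export
profile_ci.univariate_fit <- function(fit, quantity = c("h2", "a2_share",
                                                        "c2_share", "d2_share",
                                                        "e2_share"),
                                      level = 0.95, ...) {
  quantity <- match.arg(quantity)
  qhat <- .uv_share_value(fit, quantity)
  mapper <- .uv_share_map(fit$components, quantity)
  if (is.null(mapper)) {   # structurally fixed (e.g. h2 in a CE model)
    return(list(lower = qhat, upper = qhat, method = "fixed"))
  }
  ds <- fit$dataset
  covs <- fit$covariate_names
  obj <- .uv_objective(ds, fit$components, covs)
  pn <- uv_path_names(fit$components)
  np <- length(pn)
  crit <- stats::qchisq(level, df = 1)
  target <- fit$minus2lnL + crit

  mix <- attr(mapper, "mix")
  n_mix <- if (length(mix)) 1L else 0L
  s_hat <- fit$standardized
  t_hat <- 0.5
  if (n_mix == 1L) {
    tot <- sum(s_hat[paste0(mix, "2")])
    if (tot > 1e-12) {
      t_hat <- clamp(s_hat[[paste0(mix[1], "2")]] / tot, 1e-4, 1 - 1e-4)
    }
  }
  prof <- function(q) {
    q <- clamp(q, 1e-9, 1 - 1e-9)
    free0 <- c(log(max(fit$total_variance, 1e-8)),
               if (n_mix) stats::qlogis(t_hat),
               fit$mu, unname(fit$beta))
    f <- function(u) {
      V <- exp(u[1])
      t <- if (n_mix) stats::plogis(u[2]) else 0.5
      s <- mapper(q, t)
      theta <- c(sqrt(s[pn] * V), u[(1 + n_mix) + seq_len(1 + length(covs))])
      obj(theta)
    }
    stats::optim(free0, f, method = "BFGS",
                 control = list(maxit = 400, reltol = 1e-10))$value
  }
  g <- function(q) prof(q) - target
  res <- tryCatch({
    upper <- if (qhat >= 1 - 1e-6 || g(1 - 1e-7) < 0) 1 else
      stats::uniroot(g, c(qhat, 1 - 1e-7), tol = 1e-4)$root
    lower <- if (qhat <= 1e-6 || g(1e-7) < 0) 0 else
      stats::uniroot(g, c(1e-7, qhat), tol = 1e-4)$root
    list(lower = clamp(lower, 0, 1), upper = clamp(upper, 0, 1),
         method = "profile")
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)
  .uv_delta_ci(fit, quantity, level)
}

# Delta-method fallback on the path/mean parameter vector.
.uv_delta_ci <- function(fit, quantity, level) {
  obj <- .uv_objective(fit$dataset, fit$components, fit$covariate_names)
  pn <- uv_path_names(fit$components)
  np <- length(pn)
  qfun <- function(theta) {
    p <- stats::setNames(rep(0, 4), c("a", "c", "d", "e"))
    p[pn] <- theta[seq_len(np)]
    s <- p^2 / sum(p^2)
    switch(quantity,
           h2 = if (fit$components == "ADE") s[["a"]] + s[["d"]] else s[["a"]],
           a2_share = s[["a"]], c2_share = s[["c"]],
           d2_share = s[["d"]], e2_share = s[["e"]])
  }
  H <- num_hess(obj, fit$theta)
  Vtheta <- tryCatch(2 * solve(H), error = function(e) NULL)
  qhat <- .uv_share_value(fit, quantity)
  if (is.null(Vtheta)) {
    return(list(lower = NA_real_, upper = NA_real_, method = "delta-failed"))
  }
  gr <- num_grad(qfun, fit$theta)
  se <- sqrt(max(0, drop(t(gr) %*% Vtheta %*% gr)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = clamp(qhat - z * se, 0, 1),
       upper = clamp(qhat + z * se, 0, 1), method = "delta")
}
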