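#' @title Longitudinal bivariate Cholesky twin models
#'
#' @description
#' For a phenotype measured at two waves, each latent component K (A, C or
#' D, E) gets a lower-triangular 2 x 2 path matrix: `k11` loads on the
#' baseline phenotype, `k21` carries baseline influences forward to
#' follow-up, and `k22` captures influences new at follow-up. Squared paths
#' are variance components; `k11 * k21` is the cross-wave covariance carried
#' by component K. Cross-twin sharing multiplies the A block by 1 (MZ) or
#' 0.5 (DZ) and the D block by 1 or 0.25; C is shared fully and E not at
#' all.
#'
#' @name bivariate-cholesky-models
NULL

.as_path_matrix <- function(v, name) {
  if (is.null(v)) return(NULL)
  if (is.matrix(v)) {
    stopifnot(all(dim(v) == c(2, 2)))
    if (v[1, 2] != 0) stop(name, " path matrix must be lower-triangular", call. = FALSE)
    return(v)
  }
  stopifnot(length(v) == 3)
  matrix(c(v[1], v[2], 0, v[3]), 2, 2)
}

#' Construct bivariate Cholesky path parameters
#'
#' @param a,c,d,e per-component paths: either `c(k11, k21, k22)` or a 2 x 2
#'   lower-triangular matrix. `e` is required with nonzero diagonal; `c` and
#'   `d` cannot both be present.
#' @param mu per-wave grand means `c(mu1, mu2)`.
#' @param beta named covariate coefficients shared across twins and waves.
#' @return object of class `cholesky_params`.
#' @export
cholesky_params <- function(a = NULL, c = NULL, d = NULL, e,
                            mu = c(0, 0), beta = NULL) {
  if (!is.null(c) && !is.null(d)) {
    stop("C and D cannot both be present in a twin Cholesky model", call. = FALSE)
  }
  e <- .as_path_matrix(e, "e")
  if (any(diag(e) == 0)) {
    stop("e11 and e22 must be nonzero (E carries measurement error)", call. = FALSE)
  }
  p <- structure(list(a = .as_path_matrix(a, "a"), c = .as_path_matrix(c, "c"),
                      d = .as_path_matrix(d, "d"), e = e,
                      mu = mu, beta = beta),
                 class = "cholesky_params")
  for (k in c("a", "c", "d", "e")) {
    m <- p[[k]]
    if (!is.null(m) && any(diag(m) < 0)) {
      stop(k, "11 and ", k, "22 must be nonnegative (diagonal sign convention)",
           call. = FALSE)
    }
  }
  p
}

#' @export
print.cholesky_params <- function(x, ...) {
  cat("Bivariate Cholesky paths (k11, k21, k22):\n")
  for (k in c("a", "c", "d", "e")) {
    if (!is.null(x[[k]])) {
      m <- x[[k]]
      cat(sprintf("  %s: %7.4f %7.4f %7.4f\n", k, m[1, 1], m[2, 1], m[2, 2]))
    }
  }
  cat(sprintf("  means: mu1 = %.4f, mu2 = %.4f\n", x$mu[1], x$mu[2]))
  invisible(x)
}

.bv_components <- function(params) {
  Filter(Negate(is.null), params[c("a", "c", "d", "e")])
}

# 4 x 4 implied covariance, order (t1w1, t1w2, t2w1, t2w2).
.bv_sigma <- function(params, zygosity) {
  rho <- switch(zygosity, MZ = c(a = 1, c = 1, d = 1, e = 0),
                DZ = c(a = 0.5, c = 1, d = 0.25, e = 0),
                stop("unknown zygosity: ", zygosity, call. = FALSE))
  W <- matrix(0, 2, 2); X <- matrix(0, 2, 2)
  for (k in names(.bv_components(params))) {
    B <- params[[k]] %*% t(params[[k]])
    W <- W + B
    X <- X + rho[[k]] * B
  }
  rbind(cbind(W, X), cbind(X, W))
}

#' Model-implied moments of a twin pair (two waves)
#'
#' @param params a [cholesky_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param covariates optional covariate matrix: 2 x p (per twin, constant
#'   over waves) or 4 x p (rows in the order twin1-wave1, twin1-wave2,
#'   twin2-wave1, twin2-wave2), columns named as `params$beta`.
#' @return list with `mean` (length 4) and `cov` (4 x 4), coordinate order
#'   (twin1-wave1, twin1-wave2, twin2-wave1, twin2-wave2).
#' @export
expected_moments_bivariate <- function(params, zygosity, covariates = NULL) {
  sig <- .bv_sigma(params, zygosity)
  mn <- rep(params$mu, 2)
  if (!is.null(covariates) && length(params$beta)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) == 2) covariates <- covariates[c(1, 1, 2, 2), , drop = FALSE]
    mn <- mn + as.vector(covariates[, names(params$beta), drop = FALSE] %*% params$beta)
  }
  list(mean = mn, cov = sig)
}

.bv_theta_to_params <- function(theta, comps, covariates) {
  p <- list(a = NULL, c = NULL, d = NULL, e = NULL)
  i <- 0L
  for (k in comps) {
    p[[k]] <- matrix(c(theta[i + 1], theta[i + 2], 0, theta[i + 3]), 2, 2)
    i <- i + 3L
  }
  mu <- theta[i + 1:2]
  beta <- stats::setNames(theta[i + 2L + seq_along(covariates)], covariates)
  structure(list(a = p$a, c = p$c, d = p$d, e = p$e, mu = mu,
                 beta = if (length(covariates)) beta else NULL),
            class = "cholesky_params")
}

.bv_objective <- function(ds, comps, covariates) {
  y <- pheno_matrix(ds)
  zyg <- ds$pairs$zygosity
  design <- covariate_design(ds, covariates)
  for (j in seq_along(design)) {
    if (any(!is.na(y) & is.na(design[[j]]))) {
      stop("covariate '", covariates[j],
           "' is missing for twins with observed phenotype", call. = FALSE)
    }
  }
  n <- nrow(y)
  groups <- fiml_groups(y, zyg)
  function(theta) {
    params <- .bv_theta_to_params(theta, comps, covariates)
    means <- matrix(rep(params$mu, 2), n, 4, byrow = TRUE)
    for (j in seq_along(design)) {
      means <- means + params$beta[[j]] * design[[j]]
    }
    sig <- list(MZ = .bv_sigma(params, "MZ"), DZ = .bv_sigma(params, "DZ"))
    neg2ll_mvn_fiml(y, means, zyg, sig, groups)
  }
}

# Moment-based starting parameters built through the summary constructor.
.bv_starts <- function(ds, components, covariates) {
  comps <- tolower(comp_letters(components))
  y <- pheno_matrix(ds)
  n <- nrow(y)
  if (length(covariates)) {
    design <- covariate_design(ds, covariates)
    yy <- as.vector(y)
    wave <- factor(rep(c(1, 2, 1, 2), each = n))
    X <- do.call(cbind, lapply(design, as.vector))
    fit <- stats::lm(yy ~ 0 + wave + X, na.action = stats::na.exclude)
    cf <- stats::coef(fit)
    mu0 <- unname(cf[1:2])
    beta0 <- unname(cf[-(1:2)]); beta0[is.na(beta0)] <- 0
    res <- matrix(stats::residuals(fit), n, 4)
  } else {
    mu0 <- c(mean(y[, c(1, 3)], na.rm = TRUE), mean(y[, c(2, 4)], na.rm = TRUE))
    beta0 <- numeric(0)
    res <- sweep(y, 2, rep(mu0, 2))
  }
  V1 <- stats::var(as.vector(res[, c(1, 3)]), na.rm = TRUE)
  V2 <- stats::var(as.vector(res[, c(2, 4)]), na.rm = TRUE)
  mz <- ds$pairs$zygosity == "MZ"
  r_pair <- function(w, sel) safe_cor(res[sel, w], res[sel, w + 2])
  rmz <- c(r_pair(1, mz), r_pair(2, mz))
  rdz <- c(r_pair(1, !mz), r_pair(2, !mz))
  rmz[is.na(rmz)] <- 0.5; rdz[is.na(rdz)] <- 0.25
  rph <- safe_cor(c(res[, 1], res[, 3]), c(res[, 2], res[, 4]))
  R0 <- if (is.na(rph)) 0.5 else clamp(rph, -0.9, 0.95)

  shares <- sapply(1:2, function(w) {
    s <- c(a = 0, c = 0, d = 0, e = 0)
    if (components %in% c("ACE", "AE")) s["a"] <- clamp(2 * (rmz[w] - rdz[w]), 0.05, 0.85)
    if (components == "ADE") {
      s["a"] <- clamp(4 * rdz[w] - rmz[w], 0.05, 0.85)
      s["d"] <- clamp(2 * rmz[w] - 4 * rdz[w], 0.02, 0.5)
    }
    if (components %in% c("ACE", "CE")) s["c"] <- clamp(2 * rdz[w] - rmz[w], 0.02, 0.5)
    s["e"] <- max(0.05, 1 - sum(s))
    s / sum(s)
  })
  theta <- c()
  for (k in comps) {
    s1 <- shares[k, 1] * V1; s2 <- shares[k, 2] * V2
    theta <- c(theta, sqrt(s1), R0 * sqrt(s2), sqrt(s2 * (1 - R0^2)))
  }
  c(theta, mu0, beta0)
}

#' Fit a bivariate Cholesky twin model by maximum likelihood
#'
#' Maximizes the four-variate normal pair likelihood (full-information:
#' pairs missing a twin or a wave contribute the marginal density of their
#' observed entries) over the Cholesky paths of the included components plus
#' per-wave means and shared covariate coefficients. Fitted path matrices
#' are sign-normalized so the diagonals are nonnegative.
#'
#' @param ds two-wave `twin_dataset` with at least one MZ and one DZ pair.
#' @param components `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param covariates covariate names entering the means model.
#' @param n_starts number of optimizer starts.
#' @return object of class `bivariate_fit`: `params` ([cholesky_params()]),
#'   `derived` ([derive_bivariate_statistics()] output), `minus2lnL`,
#'   `n_params`, `aic`, convergence diagnostics.
#' @export
fit_bivariate <- function(ds, components = c("ACE", "ADE", "AE", "CE", "E"),
                          covariates = character(), n_starts = 5L) {
  components <- match.arg(components)
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves != 2L) stop("fit_bivariate needs two-wave data", call. = FALSE)
  check_fit_ready(ds)
  y <- pheno_matrix(ds)
  if (stats::sd(y, na.rm = TRUE) == 0) {
    stop("degenerate data: phenotype has zero variance", call. = FALSE)
  }
  comps <- tolower(comp_letters(components))
  obj <- .bv_objective(ds, comps, covariates)
  theta0 <- .bv_starts(ds, components, covariates)
  best <- .optimize_multistart(obj, theta0, n_starts = n_starts)
  theta <- best$par
  # diagonal sign convention: k11 >= 0 (flip column 1 incl. k21), k22 >= 0
  i <- 0L
  for (k in comps) {
    if (theta[i + 1] < 0) theta[i + 1:2] <- -theta[i + 1:2]
    if (theta[i + 3] < 0) theta[i + 3] <- -theta[i + 3]
    i <- i + 3L
  }
  grad <- num_grad(obj, theta)
  grad_norm <- sqrt(sum(grad^2))
  converged <- best$convergence == 0 &&
    grad_norm < 1e-5 * max(1, abs(best$value))
  if (!converged) {
    warning("fit_bivariate(", components, "): convergence not confirmed ",
            sprintf("(optim code %d, |grad| = %.3g)", best$convergence, grad_norm),
            call. = FALSE)
  }
  params <- .bv_theta_to_params(theta, comps, covariates)
  n_params <- 3L * length(comps) + 2L + length(covariates)
  structure(list(components = components, covariate_names = covariates,
                 params = params,
                 derived = derive_bivariate_statistics(params),
                 minus2lnL = best$value, n_params = n_params,
                 aic = best$value + 2 * n_params,
                 converged = converged, grad_norm = grad_norm,
                 optim_convergence = best$convergence,
                 theta = theta, dataset = ds),
            class = c("bivariate_fit", "twin_fit"))
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate %s Cholesky model: -2lnL = %.3f, AIC = %.3f (k = %d)%s\n",
              x$components, x$minus2lnL, x$aic, x$n_params,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$derived)
  invisible(x)
}

#' Fit the fully saturated two-wave model
#'
#' Per-zygosity 4-vector means and unconstrained 4 x 4 covariance matrices
#' with shared covariate coefficients; the -2 log-likelihood lower bound for
#' every bivariate Cholesky model on the same data.
#'
#' @inheritParams fit_bivariate
#' @return object of class `saturated_fit`.
#' @export
fit_saturated_bivariate <- function(ds, covariates = character()) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves != 2L) stop("fit_saturated_bivariate needs two-wave data", call. = FALSE)
  check_fit_ready(ds)
  .fit_saturated(ds, covariates, k = 4L)
}

#' Derived statistics of a bivariate Cholesky parameterization
#'
#' Per component K: baseline variance `k11^2`, follow-up variance
#' transmitted from baseline `k21^2`, follow-up-specific variance `k22^2`,
#' and cross-wave covariance `k11 * k21`. From those: total variances V1 and
#' V2, heritability at each wave, the cross-time component correlations
#' (`Ra`, `Rc`/`Rd`, `Re`), the model-implied phenotypic cross-wave
#' correlation `Rph` with its decomposition into component shares (`Pa`,
#' `Pc`/`Pd`, `Pe`), and the model-implied cross-twin cross-trait
#' correlations for MZ and DZ pairs.
#'
#' @param params a [cholesky_params()] object.
#' @return object of class `bivariate_derived`.
#' @export
derive_bivariate_statistics <- function(params) {
  stopifnot(inherits(params, "cholesky_params"))
  comps <- names(.bv_components(params))
  v1 <- v2 <- cv <- stats::setNames(rep(0, 4), c("a", "c", "d", "e"))
  for (k in comps) {
    m <- params[[k]]
    v1[k] <- m[1, 1]^2
    v2[k] <- m[2, 1]^2 + m[2, 2]^2
    cv[k] <- m[1, 1] * m[2, 1]
  }
  V1 <- sum(v1); V2 <- sum(v2)
  if (V1 <= 0 || V2 <= 0) {
    stop("total variance is zero at one wave; derived statistics undefined",
         call. = FALSE)
  }
  rk <- stats::setNames(rep(NA_real_, 4), c("a", "c", "d", "e"))
  for (k in comps) {
    rk[k] <- if (v1[k] > 0 && v2[k] > 0) cv[k] / sqrt(v1[k] * v2[k]) else 0
  }
  total_cov <- sum(cv)
  rph <- total_cov / sqrt(V1 * V2)
  pk <- stats::setNames(rep(NA_real_, 4), names(cv))
  if (abs(total_cov) > 0) pk[comps] <- cv[comps] / total_cov
  ctct <- c(MZ = (cv[["a"]] + cv[["c"]] + cv[["d"]]) / sqrt(V1 * V2),
            DZ = (0.5 * cv[["a"]] + cv[["c"]] + 0.25 * cv[["d"]]) / sqrt(V1 * V2))
  gen <- intersect(c("a", "d"), comps)
  structure(list(
    components = data.frame(
      component = comps,
      var_baseline = unname(v1[comps]),
      cov_cross = unname(cv[comps]),
      var_followup_shared = unname(sapply(comps, function(k) params[[k]][2, 1]^2)),
      var_followup_new = unname(sapply(comps, function(k) params[[k]][2, 2]^2)),
      stringsAsFactors = FALSE),
    V1 = V1, V2 = V2,
    h2_baseline = sum(v1[gen]) / V1,
    h2_followup = sum(v2[gen]) / V2,
    Ra = rk[["a"]], Rc = rk[["c"]], Rd = rk[["d"]], Re = rk[["e"]],
    Rph = rph,
    Pa = pk[["a"]], Pc = pk[["c"]], Pd = pk[["d"]], Pe = pk[["e"]],
    ctct_implied = ctct),
    class = "bivariate_derived")
}

#' @export
print.bivariate_derived <- function(x, ...) {
  cat(sprintf("V1 = %.4f, V2 = %.4f; h2 baseline = %.3f, follow-up = %.3f\n",
              x$V1, x$V2, x$h2_baseline, x$h2_followup))
  rs <- c(Ra = x$Ra, Rc = x$Rc, Rd = x$Rd, Re = x$Re, Rph = x$Rph)
  rs <- rs[!is.na(rs)]
  cat("Correlations:", paste(sprintf("%s = %.3f", names(rs), rs), collapse = ", "), "\n")
  ps <- c(Pa = x$Pa, Pc = x$Pc, Pd = x$Pd, Pe = x$Pe)
  ps <- ps[!is.na(ps)]
  if (length(ps)) {
    cat("Rph decomposition:",
        paste(sprintf("%s = %.0f%%", names(ps), 100 * ps), collapse = ", "), "\n")
  }
  cat(sprintf("Implied CTCT: MZ = %.3f, DZ = %.3f\n",
              x$ctct_implied[["MZ"]], x$ctct_implied[["DZ"]]))
  invisible(x)
}

#' Observed cross-twin cross-trait correlation
#'
#' Pearson correlation between one twin's baseline value and the co-twin's
#' follow-up value, computed on double-entered pairs (each pair contributes
#' both orderings). The confidence interval uses the Fisher z transform with
#' the number of contributing pairs (not entries) as the effective sample
#' size, which is conservative.
#'
#' @param ds two-wave `twin_dataset`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param level confidence level.
#' @return object of class `ctct_result` with `r`, `ci`, `n_pairs`.
#' @export
ctct_observed <- function(ds, zygosity = c("MZ", "DZ"), level = 0.95) {
  zygosity <- match.arg(zygosity)
  stopifnot(inherits(ds, "twin_dataset"))
  if (ds$n_waves != 2L) stop("CTCT needs two-wave data", call. = FALSE)
  p <- ds$pairs[ds$pairs$zygosity == zygosity, ]
  x <- c(p$y_1_w1, p$y_2_w1)     # twin's baseline
  yv <- c(p$y_2_w2, p$y_1_w2)    # co-twin's follow-up
  ok <- !is.na(x) & !is.na(yv)
  pair_ok <- ok[seq_len(nrow(p))] | ok[nrow(p) + seq_len(nrow(p))]
  n_pairs <- sum(pair_ok)
  if (n_pairs < 3L) {
    stop("need at least 3 complete ", zygosity, " pairs for a CTCT correlation",
         call. = FALSE)
  }
  r <- stats::cor(x[ok], yv[ok])
  if (n_pairs > 3L) {
    z <- atanh(r)
    hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n_pairs - 3)
    ci <- tanh(c(z - hw, z + hw))
  } else {
    ci <- c(-1, 1)
  }
  structure(list(zygosity = zygosity, r = r, ci = ci, n_pairs = n_pairs),
            class = "ctct_result")
}

#' @export
print.ctct_result <- function(x, ...) {
  cat(sprintf("CTCT %s: r = %s (n = %d pairs)\n", x$zygosity,
              fmt_ci(x$r, x$ci[1], x$ci[2]), x$n_pairs))
  invisible(x)
}

#' @rdname profile_ci
#' @export
profile_ci.bivariate_fit <- function(fit, quantity = c("Ra", "Rc", "Rd", "Re"),
                                     level = 0.95, ...) {
  quantity <- match.arg(quantity)
  target_k <- tolower(substr(quantity, 2, 2))
  comps <- tolower(comp_letters(fit$components))
  if (!target_k %in% comps) {
    stop("component '", toupper(target_k), "' is not in the fitted ",
         fit$components, " model", call. = FALSE)
  }
  qhat <- fit$derived[[quantity]]
  covs <- fit$covariate_names
  obj <- .bv_objective(fit$dataset, comps, covs)
  crit <- stats::qchisq(level, df = 1)
  target <- fit$minus2lnL + crit
  ti <- 3L * (match(target_k, comps) - 1L)   # offset of target paths in theta

  prof <- function(q) {
    q <- clamp(q, -1 + 1e-9, 1 - 1e-9)
    th <- fit$theta
    k11 <- max(abs(th[ti + 1]), 1e-4)
    w <- max(th[ti + 2]^2 + th[ti + 3]^2, 1e-6)
    free0 <- c(log(k11), log(w), th[-(ti + 1:3)])
    f <- function(u) {
      full <- numeric(length(fit$theta))
      full[-(ti + 1:3)] <- u[-(1:2)]
      wv <- exp(u[2])
      full[ti + 1] <- exp(u[1])
      full[ti + 2] <- q * sqrt(wv)
      full[ti + 3] <- sqrt(wv * (1 - q^2))
      obj(full)
    }
    stats::optim(free0, f, method = "BFGS",
                 control = list(maxit = 400, reltol = 1e-10))$value
  }
  g <- function(q) prof(q) - target
  res <- tryCatch({
    upper <- if (qhat >= 1 - 1e-6 || g(1 - 1e-6) < 0) 1 else
      stats::uniroot(g, c(qhat, 1 - 1e-6), tol = 1e-4)$root
    lower <- if (qhat <= -1 + 1e-6 || g(-1 + 1e-6) < 0) -1 else
      stats::uniroot(g, c(-1 + 1e-6, qhat), tol = 1e-4)$root
    list(lower = clamp(lower, -1, 1), upper = clamp(upper, -1, 1),
         method = "profile")
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)
  list(lower = NA_real_, upper = NA_real_, method = "profile-failed")
}
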