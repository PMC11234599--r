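#' @title Pipeline runners and publication-style tables
#'
#' @description
#' End-to-end runners that take a multi-metric twin table, fit the requested
#' twin models per metric, and write publication-style outputs: a
#' variance-component estimates table with confidence intervals, per-metric
#' model-comparison tables, and (for two-wave data) a correlations table
#' with CTCT, Rph, Ra/Re and the Rph decomposition, a per-wave heritability
#' table and a raw-component dump. All derived quantities in the tables are
#' recomputed from the dumped raw parameters, never by table-side arithmetic.
#'
#' @name twin-reports
NULL

.resolve_config <- function(config, dots) {
  cfg <- list()
  if (!is.null(config)) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    stopifnot(is.list(cfg))
  }
  for (nm in names(dots)) if (!is.null(dots[[nm]])) cfg[[nm]] <- dots[[nm]]
  defaults <- list(model = "auto", seed = 1L, layout = "wide",
                   covariates = character())
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  for (nm in c("input", "metrics", "out_dir")) {
    if (is.null(cfg[[nm]])) stop("config field '", nm, "' is required", call. = FALSE)
  }
  cfg
}

.metric_covariates <- function(cfg, metric) {
  cv <- cfg$covariates
  if (is.list(cv) && !is.null(names(cv))) {
    out <- cv[[metric]] %||% character()
  } else {
    out <- cv
  }
  as.character(unlist(out))
}

.metric_dataset <- function(cfg, metric, n_waves) {
  if (n_waves == 1L) {
    cmap <- c(y_1 = paste0(metric, "_1"), y_2 = paste0(metric, "_2"))
  } else {
    cmap <- stats::setNames(
      as.vector(outer(1:2, 1:2, function(t, w) sprintf("%s_%d_w%d", metric, t, w))),
      as.vector(outer(1:2, 1:2, function(t, w) sprintf("y_%d_w%d", t, w))))
  }
  read_twin_table(cfg$input, layout = cfg$layout, column_map = cmap,
                  covariates = .metric_covariates(cfg, metric),
                  variable_name = metric, delim = cfg$delim)
}

.open_log <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "run.log")
  unlink(path)
  function(...) cat(paste0(..., "\n"), file = path, append = TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  path
}

.select_or_fit_univariate <- function(ds, covs, model, log) {
  if (model == "auto") {
    sel <- select_model(ds, covs)
    tab <- as.data.frame(sel)
    for (i in seq_len(nrow(tab))) {
      log(sprintf("  %s: -2lnL = %.4f, AIC = %.4f%s", tab$model[i],
                  tab$minus2lnL[i], tab$aic[i],
                  if (!is.na(tab$p_value[i]))
                    sprintf(", LRT vs %s p = %.4g", tab$ref[i], tab$p_value[i]) else ""))
    }
    log("  selected: ", attr(sel, "selected"))
    list(components = attr(sel, "selected"), comparison = tab)
  } else {
    list(components = model, comparison = NULL)
  }
}

#' Run the univariate twin-model report
#'
#' For every metric: model selection (or a fixed family), the final fit with
#' profile CIs, one row in the estimates table (raw variance components,
#' standardized shares, h2 and e2 share with CIs) and a per-metric
#' model-comparison table. A metric that fails (e.g. zero variance) is
#' logged and skipped; the run continues.
#'
#' @param config named list or YAML file with fields `input`, `metrics`,
#'   `out_dir` and optionally `covariates` (vector, or named list per
#'   metric), `model` (`"auto"` or a family), `layout`, `delim`, `seed`.
#' @param ... individual config fields overriding `config`.
#' @return invisibly, a list with `estimates` (data.frame) and `fits`.
#' @export
run_univariate_report <- function(config = NULL, ...) {
  cfg <- .resolve_config(config, list(...))
  log <- .open_log(cfg$out_dir)
  log("univariate twin-model report; seed = ", cfg$seed)
  rows <- list(); fits <- list()
  for (metric in cfg$metrics) {
    res <- tryCatch({
      ds <- .metric_dataset(cfg, metric, n_waves = 1L)
      if (ds$n_waves != 1L) stop("two-wave input: use run_bivariate_report")
      covs <- .metric_covariates(cfg, metric)
      log(sprintf("metric %s (covariates: %s)", metric,
                  if (length(covs)) paste(covs, collapse = ", ") else "none"))
      if (!is.null(attr(ds, "sex_recoded"))) log("  ", attr(ds, "sex_recoded"))
      pick <- .select_or_fit_univariate(ds, covs, cfg$model, log)
      if (!is.null(pick$comparison)) {
        .write_tsv(pick$comparison,
                   file.path(cfg$out_dir, sprintf("comparison_%s.tsv", metric)))
      }
      fit <- fit_univariate(ds, pick$components, covs, compute_ci = TRUE)
      vc <- fit$variance_components
      sh <- fit$standardized
      list(fit = fit, row = data.frame(
        metric = metric, model = fit$components,
        a2 = vc[["a"]], c2 = vc[["c"]], d2 = vc[["d"]], e2 = vc[["e"]],
        a2_share = sh[["a2"]], c2_share = sh[["c2"]], d2_share = sh[["d2"]],
        h2 = fit$h2, h2_ci = fmt_ci(fit$h2, fit$h2_ci[1], fit$h2_ci[2]),
        e2_share = fit$e2_share,
        e2_share_ci = fmt_ci(fit$e2_share, fit$e2_share_ci[1], fit$e2_share_ci[2]),
        converged = fit$converged, stringsAsFactors = FALSE))
    }, error = function(e) {
      log("metric ", metric, ": ERROR: ", conditionMessage(e))
      warning("metric ", metric, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    rows[[metric]] <- res$row
    fits[[metric]] <- res$fit
  }
  if (!length(fits)) stop("no metric could be reported", call. = FALSE)
  estimates <- do.call(rbind, rows)
  .write_tsv(estimates, file.path(cfg$out_dir, "univariate_estimates.tsv"))
  .dump_fits_json(fits, file.path(cfg$out_dir, "univariate_fits.json"))
  log("done: ", length(fits), " of ", length(cfg$metrics), " metrics reported")
  invisible(list(estimates = estimates, fits = fits))
}

.dump_fits_json <- function(fits, path) {
  strip <- function(fit) {
    out <- unclass(fit)
    out$dataset <- NULL
    out
  }
  jsonlite::write_json(lapply(fits, strip), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
}

#' Run the longitudinal bivariate twin-model report
#'
#' For every metric with two waves of data: observed CTCT correlations per
#' zygosity (double-entry Pearson, Fisher-z CI), model selection against the
#' four-variate saturated reference, the final Cholesky fit, and derived
#' quantities (Rph, Ra/Rc/Re with profile CIs, Pa/Pc/Pe, per-wave
#' heritability, raw squared paths). Proportions are rounded to whole
#' percent in the TSV; full precision lives in the JSON dump. Metrics whose
#' wave-2 columns are absent are skipped with a warning.
#'
#' @inheritParams run_univariate_report
#' @return invisibly, a list with `correlations`, `h2`, `components`, `fits`.
#' @export
run_bivariate_report <- function(config = NULL, ...) {
  cfg <- .resolve_config(config, list(...))
  log <- .open_log(cfg$out_dir)
  log("bivariate twin-model report; seed = ", cfg$seed)
  cor_rows <- list(); h2_rows <- list(); comp_rows <- list(); fits <- list()
  for (metric in cfg$metrics) {
    res <- tryCatch({
      ds <- tryCatch(.metric_dataset(cfg, metric, n_waves = 2L),
                     error = function(e) {
        one_wave <- tryCatch({.metric_dataset(cfg, metric, 1L); TRUE},
                             error = function(e2) FALSE)
        if (one_wave) {
          stop("metric ", metric, " has only one wave of data; ",
               "use run_univariate_report", call. = FALSE)
        }
        stop(e)
      })
      covs <- .metric_covariates(cfg, metric)
      log(sprintf("metric %s (covariates: %s)", metric,
                  if (length(covs)) paste(covs, collapse = ", ") else "none"))
      ct_mz <- ctct_observed(ds, "MZ")
      ct_dz <- ctct_observed(ds, "DZ")
      pick <- .select_or_fit_univariate(ds, covs, cfg$model, log)
      if (!is.null(pick$comparison)) {
        .write_tsv(pick$comparison,
                   file.path(cfg$out_dir, sprintf("comparison_%s.tsv", metric)))
      }
      fit <- fit_bivariate(ds, pick$components, covs)
      dv <- derive_bivariate_statistics(fit$params)  # recomputed, not copied
      ci_ra <- if (!is.na(dv$Ra)) profile_ci(fit, "Ra") else NULL
      ci_re <- profile_ci(fit, "Re")
      pct <- function(x) if (is.na(x)) NA_character_ else sprintf("%.0f%%", 100 * x)
      row <- data.frame(
        metric = metric, model = fit$components,
        ctct_mz = fmt_ci(ct_mz$r, ct_mz$ci[1], ct_mz$ci[2]),
        ctct_dz = fmt_ci(ct_dz$r, ct_dz$ci[1], ct_dz$ci[2]),
        Rph = dv$Rph,
        Ra = if (is.null(ci_ra)) NA_character_
             else fmt_ci(dv$Ra, ci_ra$lower, ci_ra$upper),
        Rc = if (is.na(dv$Rc)) NA_real_ else dv$Rc,
        Re = fmt_ci(dv$Re, ci_re$lower, ci_re$upper),
        Pa = pct(dv$Pa), Pc = pct(dv$Pc), Pe = pct(dv$Pe),
        stringsAsFactors = FALSE)
      comp <- cbind(metric = metric, dv$components)
      list(fit = fit, row = row, comp = comp,
           h2 = data.frame(metric = metric, h2_baseline = dv$h2_baseline,
                           h2_followup = dv$h2_followup,
                           stringsAsFactors = FALSE))
    }, error = function(e) {
      log("metric ", metric, ": ERROR: ", conditionMessage(e))
      warning("metric ", metric, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    cor_rows[[metric]] <- res$row
    h2_rows[[metric]] <- res$h2
    comp_rows[[metric]] <- res$comp
    fits[[metric]] <- res$fit
  }
  if (!length(fits)) stop("no metric could be reported", call. = FALSE)
  correlations <- do.call(rbind, cor_rows)
  h2 <- do.call(rbind, h2_rows)
  components <- do.call(rbind, comp_rows)
  .write_tsv(correlations, file.path(cfg$out_dir, "bivariate_correlations.tsv"))
  .write_tsv(h2, file.path(cfg$out_dir, "bivariate_h2.tsv"))
  .write_tsv(components, file.path(cfg$out_dir, "bivariate_components.tsv"))
  .dump_fits_json(fits, file.path(cfg$out_dir, "bivariate_fits.json"))
  log("done: ", length(fits), " of ", length(cfg$metrics), " metrics reported")
  invisible(list(correlations = correlations, h2 = h2,
                 components = components, fits = fits))
}
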