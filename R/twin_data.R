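#' Twin-pair datasets
#'
#' A `twin_dataset` holds same-sex twin pairs measured on one phenotype at one
#' or two waves, together with per-twin covariates. Internally one row per
#' pair is kept, with phenotype columns `y_<twin>_w<wave>` and covariate
#' columns `<name>_<twin>` (constant over waves) or `<name>_<twin>_w<wave>`
#' (wave-varying, e.g. chronological age at each survey).
#'
#' @param pairs data.frame with columns `pair_id`, `zygosity` (`"MZ"`/`"DZ"`),
#'   phenotype columns `y_1_w1`, `y_2_w1` (and `y_1_w2`, `y_2_w2` for two
#'   waves) plus any covariate columns.
#' @param variable_name label of the modelled phenotype.
#' @param covariate_names character vector of covariate base names; inferred
#'   from the remaining columns when `NULL`.
#' @return An object of class `twin_dataset` with fields `pairs`, `n_waves`,
#'   `variable_name` and `covariate_names`.
#' @examples
#' d <- data.frame(pair_id = c("p1", "p2"), zygosity = c("MZ", "DZ"),
#'                 y_1_w1 = c(0.2, -1), y_2_w1 = c(0.1, 0.5))
#' twin_dataset(d)
#' @export
twin_dataset <- function(pairs, variable_name = "y", covariate_names = NULL) {
  stopifnot(is.data.frame(pairs))
  for (col in c("pair_id", "zygosity")) {
    if (!col %in% names(pairs)) {
      stop("schema error: required column '", col, "' is missing", call. = FALSE)
    }
  }
  pairs$pair_id <- as.character(pairs$pair_id)
  n_waves <- if (all(c("y_1_w2", "y_2_w2") %in% names(pairs))) 2L else 1L
  ycols <- as.vector(outer(1:2, seq_len(n_waves),
                           function(t, w) sprintf("y_%d_w%d", t, w)))
  missing_y <- setdiff(ycols, names(pairs))
  if (length(missing_y)) {
    stop("schema error: phenotype column(s) ", paste(missing_y, collapse = ", "),
         " missing", call. = FALSE)
  }
  if (anyDuplicated(pairs$pair_id)) {
    stop("integrity error: duplicate pair_id: ",
         paste(unique(pairs$pair_id[duplicated(pairs$pair_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !pairs$zygosity %in% c("MZ", "DZ")
  if (any(bad)) {
    stop("integrity error: zygosity must be 'MZ' or 'DZ', got: ",
         paste(unique(pairs$zygosity[bad]), collapse = ", "), call. = FALSE)
  }
  if (is.null(covariate_names)) {
    other <- setdiff(names(pairs), c("pair_id", "zygosity", ycols))
    covariate_names <- unique(sub("_(1|2)(_w[0-9]+)?$", "", other))
  }
  for (nm in covariate_names) {
    for (t in 1:2) {
      plain <- sprintf("%s_%d", nm, t)
      waved <- sprintf("%s_%d_w%d", nm, t, seq_len(n_waves))
      if (!plain %in% names(pairs) && !all(waved %in% names(pairs))) {
        stop("schema error: covariate '", nm, "' lacks columns for twin ", t,
             call. = FALSE)
      }
    }
  }
  ds <- structure(list(pairs = pairs, n_waves = n_waves,
                       variable_name = variable_name,
                       covariate_names = covariate_names),
                  class = "twin_dataset")
  if ("sex" %in% covariate_names) ds <- .check_sex(ds)
  ds
}

# Same-sex design: remap {1,2} sex coding to {0,1} and reject pairs whose
# twins disagree on sex.
.check_sex <- function(ds) {
  cols <- grep("^sex_(1|2)(_w[0-9]+)?$", names(ds$pairs), value = TRUE)
  vals <- unlist(ds$pairs[cols], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("validation error: sex must be coded 0/1 or 1/2", call. = FALSE)
  }
  if (any(vals == 2)) {       # 1/2 coding
    for (col in cols) ds$pairs[[col]] <- ds$pairs[[col]] - 1
    attr(ds, "sex_recoded") <- "sex recoded from 1/2 to 0/1"
  }
  s1 <- ds$pairs[[grep("^sex_1", cols, value = TRUE)[1]]]
  s2 <- ds$pairs[[grep("^sex_2", cols, value = TRUE)[1]]]
  bad <- !is.na(s1) & !is.na(s2) & s1 != s2
  if (any(bad)) {
    stop("validation error: opposite-sex pair(s): ",
         paste(ds$pairs$pair_id[bad], collapse = ", "), call. = FALSE)
  }
  ds
}

#' @export
print.twin_dataset <- function(x, ...) {
  n <- nrow(x$pairs)
  cat(sprintf("Twin dataset: %d pairs (%d MZ, %d DZ), %d wave%s, phenotype '%s'\n",
              n, sum(x$pairs$zygosity == "MZ"), sum(x$pairs$zygosity == "DZ"),
              x$n_waves, if (x$n_waves > 1) "s" else "", x$variable_name))
  if (length(x$covariate_names)) {
    cat("Covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  }
  invisible(x)
}

# Phenotype matrix in model order: (twin1 w1 [, twin1 w2], twin2 w1 [, w2]).
pheno_matrix <- function(ds) {
  cols <- as.vector(t(outer(1:2, seq_len(ds$n_waves),
                            function(t, w) sprintf("y_%d_w%d", t, w))))
  as.matrix(ds$pairs[cols])
}

# Covariate value matrix (n pairs x 1) for twin t at wave w; wave-specific
# column wins over the per-twin constant column.
cov_values <- function(ds, name, twin, wave = 1L) {
  waved <- sprintf("%s_%d_w%d", name, twin, wave)
  plain <- sprintf("%s_%d", name, twin)
  col <- if (waved %in% names(ds$pairs)) waved else plain
  if (!col %in% names(ds$pairs)) {
    stop("covariate '", name, "' not found for twin ", twin, call. = FALSE)
  }
  ds$pairs[[col]]
}

# n x k matrix of mean-model covariate contributions columns in model order.
covariate_design <- function(ds, covariate_names) {
  k <- 2L * ds$n_waves
  lapply(covariate_names, function(nm) {
    m <- matrix(NA_real_, nrow(ds$pairs), k)
    j <- 0L
    for (t in 1:2) for (w in seq_len(ds$n_waves)) {
      j <- j + 1L
      m[, j] <- cov_values(ds, nm, t, w)
    }
    m
  })
}

check_fit_ready <- function(ds) {
  if (sum(ds$pairs$zygosity == "MZ") < 1L || sum(ds$pairs$zygosity == "DZ") < 1L) {
    stop("validation error: at least one MZ and one DZ pair are required",
         call. = FALSE)
  }
  invisible(ds)
}

#' Swap twin order within pairs
#'
#' Twin order within a pair is arbitrary; all likelihoods in the package are
#' invariant to it. This helper exchanges the twin-1 and twin-2 slots
#' (phenotypes and covariates), which is useful for verifying that property.
#'
#' @param ds a `twin_dataset`.
#' @param which integer indices of pairs to swap (default: all pairs).
#' @return The dataset with the requested pairs swapped.
#' @export
swap_twin_order <- function(ds, which = seq_len(nrow(ds$pairs))) {
  p <- ds$pairs
  for (col1 in grep("_1(_w[0-9]+)?$", names(p), value = TRUE)) {
    col2 <- sub("_1(?=($|_w))", "_2", col1, perl = TRUE)
    tmp <- p[[col1]][which]
    p[[col1]][which] <- p[[col2]][which]
    p[[col2]][which] <- tmp
  }
  ds$pairs <- p
  ds
}

#' Group summaries of a twin dataset
#'
#' Per zygosity group and wave: number of pairs, number of non-missing
#' individual measurements, phenotype mean and standard deviation (sample SD,
#' n - 1), and the within-pair correlation over complete pairs, computed on
#' double-entered pairs (each pair contributes both twin orderings) so it
#' does not depend on the arbitrary twin order. Undefined correlations
#' (fewer than two complete pairs, or zero variance) are reported as `NA`
#' rather than raising an error.
#'
#' @param ds a `twin_dataset`.
#' @return data.frame with one row per zygosity and wave.
#' @export
twin_summary <- function(ds) {
  out <- expand.grid(zygosity = c("MZ", "DZ"), wave = seq_len(ds$n_waves),
                     stringsAsFactors = FALSE)
  stats_rows <- lapply(seq_len(nrow(out)), function(i) {
    z <- out$zygosity[i]; w <- out$wave[i]
    sel <- ds$pairs$zygosity == z
    y1 <- ds$pairs[[sprintf("y_1_w%d", w)]][sel]
    y2 <- ds$pairs[[sprintf("y_2_w%d", w)]][sel]
    vals <- c(y1, y2)
    data.frame(n_pairs = sum(sel), n_individuals = sum(!is.na(vals)),
               mean = if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_,
               sd = if (sum(!is.na(vals)) > 1) stats::sd(vals, na.rm = TRUE) else NA_real_,
               r = safe_cor(c(y1, y2), c(y2, y1)))
  })
  cbind(out, do.call(rbind, stats_rows))
}

#' @export
summary.twin_dataset <- function(object, ...) twin_summary(object)
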