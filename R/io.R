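#' Read a twin-pair table
#'
#' Reads a delimited (CSV/TSV, UTF-8, header row required) table of twin
#' pairs in either layout:
#'
#' * `wide`: one row per pair with columns `pair_id`, `zygosity`, phenotype
#'   columns `y_1`, `y_2` (one wave) or `y_1_w1`, `y_1_w2`, `y_2_w1`,
#'   `y_2_w2` (two waves), and covariate columns `<name>_1`/`<name>_2`
#'   (optionally `<name>_<twin>_w<wave>`).
#' * `long`: one row per twin per wave with columns `pair_id`, `zygosity`,
#'   `twin` (1/2), `y`, optionally `wave` (1/2), and one plain column per
#'   covariate.
#'
#' Pairs with a missing co-twin row are retained with the missing slot set to
#' `NA`. Empty fields and `"NA"` are read as missing.
#'
#' @param path file to read.
#' @param layout `"wide"` or `"long"`.
#' @param column_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(y_1 = "pheno.t1")`.
#' @param covariates covariate base names; inferred from leftover columns
#'   when `NULL`.
#' @param variable_name phenotype label stored on the dataset.
#' @param delim field delimiter; inferred from the extension (`.tsv`/`.txt`
#'   tab, otherwise comma) when `NULL`.
#' @param zygosity_codes named list of accepted tokens per zygosity
#'   (case-insensitive), e.g. `list(MZ = c("MZ", "1"), DZ = c("DZ", "2"))`.
#' @return A validated [twin_dataset()] preserving file order.
#' @export
read_twin_table <- function(path, layout = c("wide", "long"), column_map = NULL,
                            covariates = NULL, variable_name = "y",
                            delim = NULL,
                            zygosity_codes = list(MZ = "MZ", DZ = "DZ")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% .infer_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL,
                           quote = "\"", comment.char = "")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      j <- match(column_map[[canon]], names(raw))
      if (is.na(j)) {
        stop("schema error: mapped column '", column_map[[canon]],
             "' not found in ", path, call. = FALSE)
      }
      names(raw)[j] <- canon
    }
  }
  for (col in c("pair_id", "zygosity")) {
    if (!col %in% names(raw)) {
      stop("schema error: required column '", col, "' missing in ", path,
           call. = FALSE)
    }
  }
  raw$zygosity <- .decode_zygosity(raw$zygosity, zygosity_codes)
  if (layout == "wide") {
    .read_wide(raw, covariates, variable_name)
  } else {
    .read_long(raw, covariates, variable_name)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.infer_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.decode_zygosity <- function(x, codes) {
  out <- rep(NA_character_, length(x))
  for (z in c("MZ", "DZ")) {
    out[toupper(trimws(x)) %in% toupper(codes[[z]])] <- z
  }
  bad <- is.na(out) & !is.na(x) & trimws(x) != ""
  if (any(bad)) {
    stop("integrity error: unrecognized zygosity token(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

# Parse a character column as numeric; error names the offending data row.
.parse_num <- function(x, colname, na_tokens = c("", "NA")) {
  x <- trimws(x)
  x[x %in% na_tokens] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop("parse error: non-numeric value '", x[bad[1]], "' in column '",
         colname, "', row ", bad[1], call. = FALSE)
  }
  out
}

.read_wide <- function(raw, covariates, variable_name) {
  if (all(c("y_1", "y_2") %in% names(raw))) {
    names(raw)[names(raw) == "y_1"] <- "y_1_w1"
    names(raw)[names(raw) == "y_2"] <- "y_2_w1"
  }
  ycols <- grep("^y_(1|2)_w[12]$", names(raw), value = TRUE)
  if (!all(c("y_1_w1", "y_2_w1") %in% ycols)) {
    stop("schema error: wide layout needs phenotype columns y_1/y_2 ",
         "or y_<twin>_w<wave>", call. = FALSE)
  }
  numcols <- setdiff(names(raw), c("pair_id", "zygosity"))
  for (col in numcols) raw[[col]] <- .parse_num(raw[[col]], col)
  twin_dataset(raw, variable_name = variable_name,
               covariate_names = covariates)
}

.read_long <- function(raw, covariates, variable_name) {
  for (col in c("twin", "y")) {
    if (!col %in% names(raw)) {
      stop("schema error: long layout needs column '", col, "'", call. = FALSE)
    }
  }
  raw$twin <- .parse_num(raw$twin, "twin")
  if (!all(raw$twin %in% c(1, 2))) {
    stop("integrity error: twin index must be 1 or 2", call. = FALSE)
  }
  raw$wave <- if ("wave" %in% names(raw)) .parse_num(raw$wave, "wave") else 1
  if (!all(raw$wave %in% c(1, 2))) {
    stop("integrity error: wave must be 1 or 2", call. = FALSE)
  }
  key <- paste(raw$pair_id, raw$twin, raw$wave)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (pair_id, twin, wave) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  raw$y <- .parse_num(raw$y, "y")
  n_waves <- as.integer(max(raw$wave))
  cov_names <- covariates %||%
    setdiff(names(raw), c("pair_id", "zygosity", "twin", "wave", "y"))
  for (col in cov_names) raw[[col]] <- .parse_num(raw[[col]], col)

  ids <- unique(raw$pair_id)
  pairs <- data.frame(pair_id = ids, zygosity = NA_character_,
                      stringsAsFactors = FALSE)
  for (t in 1:2) for (w in seq_len(n_waves)) {
    pairs[[sprintf("y_%d_w%d", t, w)]] <- NA_real_
  }
  # covariates first gathered per twin per wave, collapsed afterwards
  for (nm in cov_names) for (t in 1:2) for (w in seq_len(n_waves)) {
    pairs[[sprintf("%s_%d_w%d", nm, t, w)]] <- NA_real_
  }
  row_of <- match(raw$pair_id, ids)
  for (i in seq_len(nrow(raw))) {
    r <- row_of[i]; t <- raw$twin[i]; w <- raw$wave[i]
    zyg <- raw$zygosity[i]
    if (is.na(pairs$zygosity[r])) {
      pairs$zygosity[r] <- zyg
    } else if (!is.na(zyg) && pairs$zygosity[r] != zyg) {
      stop("integrity error: pair ", raw$pair_id[i],
           " has inconsistent zygosity", call. = FALSE)
    }
    pairs[[sprintf("y_%d_w%d", t, w)]][r] <- raw$y[i]
    for (nm in cov_names) {
      pairs[[sprintf("%s_%d_w%d", nm, t, w)]][r] <- raw[[nm]][i]
    }
  }
  # collapse covariates that do not vary over waves to a single column
  for (nm in cov_names) for (t in 1:2) {
    wcols <- sprintf("%s_%d_w%d", nm, t, seq_len(n_waves))
    m <- as.matrix(pairs[wcols])
    constant <- apply(m, 1L, function(v) length(unique(v[!is.na(v)])) <= 1L)
    if (all(constant)) {
      pairs[[sprintf("%s_%d", nm, t)]] <-
        apply(m, 1L, function(v) if (all(is.na(v))) NA_real_ else v[!is.na(v)][1])
      pairs <- pairs[setdiff(names(pairs), wcols)]
    }
  }
  twin_dataset(pairs, variable_name = variable_name,
               covariate_names = if (length(cov_names)) cov_names else NULL)
}

#' Write a twin-pair table
#'
#' Inverse of [read_twin_table()]: `read_twin_table(write_twin_table(ds))`
#' reproduces the dataset exactly (values, pair order, missingness). Missing
#' values are written as `"NA"`.
#'
#' @param ds a `twin_dataset`.
#' @param path output file; delimiter inferred from the extension unless
#'   `delim` is given.
#' @param layout `"wide"` or `"long"`.
#' @param delim field delimiter override.
#' @return `path`, invisibly.
#' @export
write_twin_table <- function(ds, path, layout = c("wide", "long"),
                             delim = NULL) {
  layout <- match.arg(layout)
  delim <- delim %||% .infer_delim(path)
  tab <- if (layout == "wide") .as_wide_table(ds) else .as_long_table(ds)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = delim, row.names = FALSE,
                       quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

.as_wide_table <- function(ds) {
  tab <- ds$pairs
  if (ds$n_waves == 1L) {
    names(tab)[names(tab) == "y_1_w1"] <- "y_1"
    names(tab)[names(tab) == "y_2_w1"] <- "y_2"
  }
  tab
}

.as_long_table <- function(ds) {
  p <- ds$pairs
  rows <- list()
  for (i in seq_len(nrow(p))) for (t in 1:2) for (w in seq_len(ds$n_waves)) {
    row <- data.frame(pair_id = p$pair_id[i], zygosity = p$zygosity[i],
                      twin = t, wave = w,
                      y = p[[sprintf("y_%d_w%d", t, w)]][i],
                      stringsAsFactors = FALSE)
    for (nm in ds$covariate_names) {
      row[[nm]] <- cov_values(ds, nm, t, w)[i]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (ds$n_waves == 1L) out$wave <- NULL
  out
}
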