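test_that("wide and long reads agree and validate zygosity", {
  wide <- tempfile(fileext = ".csv")
  writeLines(c("pair_id,zygosity,y1,y2",
               "p1,MZ,1.5,1.2",
               "p2,DZ,-0.3,0.4"), wide)
  ds <- read_twin_table(wide, "wide", column_map = c(y_1 = "y1", y_2 = "y2"))
  expect_s3_class(ds, "twin_dataset")
  expect_equal(nrow(ds$pairs), 2L)
  expect_equal(ds$n_waves, 1L)
  expect_equal(ds$pairs$y_1_w1, c(1.5, -0.3))

  long <- tempfile(fileext = ".csv")
  writeLines(c("pair_id,zygosity,twin,y",
               "p1,MZ,1,1.5", "p1,MZ,2,1.2",
               "p2,DZ,1,-0.3", "p2,DZ,2,0.4"), long)
  ds_long <- read_twin_table(long, "long")
  expect_equal(ds_long$pairs, ds$pairs)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("pair_id,zygosity,y_1,y_2", "p1,OS,1,2"), bad)
  expect_error(read_twin_table(bad, "wide"), "zygosity")
})

test_that("schema, integrity and parse errors are specific", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("pair_id,y_1,y_2", "p1,1,2"), f)
  expect_error(read_twin_table(f, "wide"), "zygosity")

  writeLines(c("pair_id,zygosity,y_1,y_2", "p1,MZ,1,2", "p1,MZ,3,4"), f)
  expect_error(read_twin_table(f, "wide"), "duplicate pair_id")

  writeLines(c("pair_id,zygosity,twin,y",
               "p1,MZ,1,1", "p1,MZ,1,2"), f)
  expect_error(read_twin_table(f, "long"), "duplicate \\(pair_id, twin, wave\\)")

  writeLines(c("pair_id,zygosity,y_1,y_2", "p1,MZ,1,2", "p2,DZ,oops,4"), f)
  expect_error(read_twin_table(f, "wide"), "non-numeric value 'oops'.*row 2")
})

test_that("round-trips are lossless in both layouts, with missing values", {
  ds <- simulate_univariate_twins(5, 4, a2 = 0.4, e2 = 0.6, seed = 5,
                                  sex_p = 0.5)
  ds$pairs$y_2_w1[2] <- NA    # flagged missing co-twin slot
  for (layout in c("wide", "long")) {
    f <- tempfile(fileext = ".csv")
    write_twin_table(ds, f, layout)
    back <- read_twin_table(f, layout)
    expect_equal(back$pairs, ds$pairs, tolerance = 1e-12)
    expect_equal(back$n_waves, ds$n_waves)
  }
  # two-wave round trip with a wave-varying covariate
  p <- cholesky_params(a = c(0.6, 0.4, 0.3), e = c(0.7, 0.2, 0.6))
  ds2 <- simulate_bivariate_twins(4, 3, p, seed = 8, age_range = c(30, 60))
  ds2$pairs$y_1_w2[1] <- NA
  for (layout in c("wide", "long")) {
    f <- tempfile(fileext = ".csv")
    write_twin_table(ds2, f, layout)
    back <- read_twin_table(f, layout)
    expect_equal(back$pairs[sort(names(back$pairs))],
                 ds2$pairs[sort(names(ds2$pairs))], tolerance = 1e-12)
  }
})

test_that("empty dataset writes a header-only file and round-trips", {
  ds <- twin_dataset(data.frame(pair_id = character(), zygosity = character(),
                                y_1_w1 = numeric(), y_2_w1 = numeric()))
  f <- tempfile(fileext = ".csv")
  write_twin_table(ds, f, "wide")
  expect_equal(length(readLines(f)), 1L)
  back <- read_twin_table(f, "wide")
  expect_equal(nrow(back$pairs), 0L)
})

test_that("group summaries match a brute-force recomputation", {
  # constant input: SD 0, correlation undefined
  ds <- make_uv_ds(rep(5, 4), rep(5, 4), c("MZ", "MZ", "DZ", "DZ"))
  s <- twin_summary(ds)
  expect_equal(s$mean, rep(5, 2))
  expect_equal(s$sd, rep(0, 2))
  expect_true(all(is.na(s$r)))

  # identical MZ twins: r exactly 1
  y <- rnorm(6)
  ds <- make_uv_ds(c(y, rnorm(3)), c(y, rnorm(3)), rep(c("MZ", "DZ"), c(6, 3)))
  expect_equal(twin_summary(ds)$r[1], 1.0)

  # 10-pair fixture vs direct spreadsheet-style formulas (double entry for r)
  set.seed(42)
  y1 <- rnorm(10); y2 <- 0.5 * y1 + rnorm(10)
  zyg <- rep(c("MZ", "DZ"), 5)
  ds <- make_uv_ds(y1, y2, zyg)
  s <- twin_summary(ds)
  for (z in c("MZ", "DZ")) {
    sel <- zyg == z
    vals <- c(y1[sel], y2[sel])
    n <- length(vals); m <- sum(vals) / n
    sdv <- sqrt(sum((vals - m)^2) / (n - 1))
    x <- c(y1[sel], y2[sel]); yy <- c(y2[sel], y1[sel])
    r <- sum((x - mean(x)) * (yy - mean(yy))) /
      sqrt(sum((x - mean(x))^2) * sum((yy - mean(yy))^2))
    expect_equal(s$mean[s$zygosity == z], m)
    expect_equal(s$sd[s$zygosity == z], sdv)
    expect_equal(s$r[s$zygosity == z], r)
  }
})

test_that("summaries are invariant to twin order within pairs", {
  ds <- simulate_univariate_twins(20, 15, a2 = 0.5, e2 = 0.5, seed = 3)
  swapped <- swap_twin_order(ds, which = c(1, 4, 9, 30))
  expect_equal(twin_summary(swapped), twin_summary(ds))
})

test_that("sex is recoded from 1/2 and opposite-sex pairs are rejected", {
  df <- data.frame(pair_id = c("a", "b"), zygosity = c("MZ", "DZ"),
                   y_1_w1 = c(1, 2), y_2_w1 = c(1, 2),
                   sex_1 = c(1, 2), sex_2 = c(1, 2))
  ds <- twin_dataset(df)
  expect_equal(ds$pairs$sex_1, c(0, 1))
  expect_match(attr(ds, "sex_recoded"), "recoded")

  df$sex_1 <- c(0, 1); df$sex_2 <- c(0, 0)
  expect_error(twin_dataset(df), "opposite-sex")
})
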