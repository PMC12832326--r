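test_that("age-group bins follow the pubertal-stage bounds", {
  expect_equal(assign_age_group(c(0, 5.9, 6.0, 7.9, 8.0, 10.9, 11.0, 12.9,
                                  13.0, 14.9, 15.0, 18.0)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L))
  expect_error(assign_age_group(18.01), class = "phalanx_age_error")
  expect_error(assign_age_group(-0.1), class = "phalanx_age_error")
})

test_that("union trimming of i.i.d. normal triples retains ~92.85%", {
  set.seed(101)
  n <- 1e4
  ratios <- tibble::tibble(subject_id = as.character(seq_len(n)),
                           r43mc = rnorm(n), r53mc = rnorm(n),
                           r53mp = rnorm(n))
  trimmed <- trim_outliers(ratios, trim_limit = 2.25)
  retained_frac <- trimmed$report$n_retained / n
  expect_equal(retained_frac, (1 - 2 * pnorm(-2.25))^3, tolerance = 0.011)
  # report bookkeeping: union <= sum of per-ratio counts; totals add up
  r <- trimmed$report
  expect_lte(r$n_excluded_total, sum(r$n_excluded_per_ratio))
  expect_equal(r$n_retained + r$n_excluded_total, r$n_input)
  expect_equal(nrow(r$excluded), r$n_excluded_total)
})

test_that("degenerate ratio distributions are guarded, not trimmed", {
  set.seed(2)
  ratios <- tibble::tibble(subject_id = as.character(1:20),
                           r43mc = 0.9, r53mc = rnorm(20, 0.8, 0.02),
                           r53mp = rnorm(20, 0.6, 0.05))
  expect_warning(trimmed <- trim_outliers(ratios), "r43mc has zero SD")
  expect_equal(unname(trimmed$report$n_excluded_per_ratio["r43mc"]), 0)
  # fully constant cohort: no exclusions at all
  constant <- tibble::tibble(subject_id = as.character(1:20),
                             r43mc = 0.9, r53mc = 0.8, r53mp = 0.6)
  trimmed2 <- suppressWarnings(trim_outliers(constant))
  expect_equal(trimmed2$report$n_excluded_total, 0L)
})

test_that("a subject exactly at the limit is retained (strict inequality)", {
  set.seed(5)
  n <- 500
  ratios <- tibble::tibble(subject_id = as.character(seq_len(n)),
                           r43mc = rnorm(n), r53mc = rnorm(n),
                           r53mp = rnorm(n))
  # set the limit to the exact maximum |z| of the sample: nothing excluded
  z_max <- max(abs(scale(as.matrix(ratios[, 2:4]))))
  trimmed <- trim_outliers(ratios, trim_limit = z_max)
  expect_equal(trimmed$report$n_excluded_total, 0L)
  # an epsilon below the max excludes at least the extreme subject
  trimmed2 <- trim_outliers(ratios, trim_limit = z_max * (1 - 1e-12))
  expect_gte(trimmed2$report$n_excluded_total, 1L)
})

test_that("trimming is single-pass: decisions depend on input moments only", {
  set.seed(8)
  n <- 2000
  ratios <- tibble::tibble(subject_id = as.character(seq_len(n)),
                           r43mc = rnorm(n), r53mc = rnorm(n),
                           r53mp = rnorm(n))
  first <- trim_outliers(ratios)
  # re-trimming the retained sample excludes MORE (moments shrink), which is
  # exactly why the builder applies one pass on the input moments
  second <- trim_outliers(first$retained)
  expect_gt(second$report$n_excluded_total, 0L)
  # the builder's own exclusion set is reproducible from input moments
  z <- abs(scale(as.matrix(ratios[, 2:4])))
  expect_equal(first$report$n_excluded_total, sum(apply(z > 2.25, 1, any)))
})

test_that("reference table computes group stats by hand-checkable arithmetic", {
  ratios <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                           r43mc = c(0.8, 0.9, 0.8, 0.9),
                           r53mc = c(0.8, 0.9, 0.8, 0.9),
                           r53mp = c(0.5, 0.6, 0.5, 0.6))
  meta <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                         bone_age = c(3, 3, 9, 9))
  tab <- build_reference(ratios, meta)
  g1 <- tab$groups[tab$groups$age_group == 1 & tab$groups$ratio == "r43mc", ]
  expect_equal(g1$mean, 0.85)
  expect_equal(g1$sd, sd(c(0.8, 0.9)))
  expect_equal(g1$n, 2L)
  # permutation invariance
  perm <- sample(4)
  tab2 <- build_reference(ratios[perm, ], meta[perm, ])
  expect_equal(tab$groups, tab2$groups)
  expect_equal(tab$pooled, tab2$pooled)
  # empty groups carry n = 0 and NA sd
  g2 <- tab$groups[tab$groups$age_group == 2, ]
  expect_true(all(g2$n == 0L))
  expect_true(all(is.na(g2$sd)))
})

test_that("reference JSON round trip is lossless", {
  fx <- default_reference_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_reference(fx$table, path)
  back <- read_reference(path)
  expect_equal(back$groups$mean, fx$table$groups$mean, tolerance = 1e-12)
  expect_equal(back$groups$sd, fx$table$groups$sd, tolerance = 1e-12)
  expect_equal(back$pooled$mean, fx$table$pooled$mean, tolerance = 1e-12)
  expect_identical(back$provenance$input_hash, fx$table$provenance$input_hash)
  # wrong schema version is refused
  raw <- jsonlite::read_json(path)
  raw$format <- "phalanx-ref/999"
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_reference(path), class = "phalanx_version_error")
})

test_that("distribution diagnostics recover known shapes", {
  set.seed(31)
  x <- rnorm(1e5)
  d <- distribution_diagnostics(x)
  expect_equal(d$skewness, 0, tolerance = 0.02)
  expect_equal(d$excess_kurtosis, 0, tolerance = 0.05)
  e <- distribution_diagnostics(rexp(1e5))
  expect_equal(e$skewness, 2, tolerance = 0.1)
  expect_error(distribution_diagnostics(rep(1, 10)),
               class = "phalanx_diagnostics_error")
  expect_error(distribution_diagnostics(c(1, 2, 3)),
               class = "phalanx_diagnostics_error")
})

test_that("simulated reference ratios pass near-normality diagnostics", {
  fx <- default_reference_fixture()
  d <- ratio_diagnostics(fx$trimmed$retained)
  expect_true(all(abs(d$skewness) < 0.6))
  expect_true(all(abs(d$excess_kurtosis) < 0.6))
})
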