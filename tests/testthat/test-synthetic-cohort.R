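test_that("noise calibration solves the shared-denominator moment system", {
  out <- calibrate_reference_noise(0.019 / 0.889, 0.022 / 0.822, 0.49)
  expect_equal(unname(out), c(0.0167, 0.0133, 0.0209), tolerance = 0.01)
  # the closed form satisfies the three equations exactly
  expect_equal(out[["sd3"]]^2 + out[["sd4"]]^2, (0.019 / 0.889)^2)
  expect_equal(out[["sd3"]]^2 + out[["sd5"]]^2, (0.022 / 0.822)^2)
  expect_equal(out[["sd3"]]^2, 0.49 * (0.019 / 0.889) * (0.022 / 0.822))
})

test_that("zero target correlation puts all noise on the numerators", {
  out <- calibrate_reference_noise(0.02, 0.02, 0)
  expect_equal(unname(out), c(0, 0.02, 0.02))
})

test_that("correlation beyond the shared-variance bound is infeasible", {
  # corr * cv43 * cv53 > cv43^2 forces sd4^2 < 0
  expect_error(calibrate_reference_noise(0.01, 0.03, 0.5),
               class = "phalanx_infeasible_error")
  expect_error(calibrate_reference_noise(0.01, 0.01, 1.2),
               class = "phalanx_infeasible_error")
})

test_that("calibrated noise reproduces CVs and MC correlation at scale", {
  cv43 <- 0.019 / 0.889; cv53 <- 0.022 / 0.822
  cfg <- generator_config(ref_n = 1e5, seed = 11)
  cohort <- simulate_reference_cohort(cfg)
  ratios <- compute_ratios(cohort$lengths)
  # within-group CVs (pool groups 1-5 which share the ratio mean)
  grp <- cohort$subjects$age_group
  sub <- ratios[grp <= 5, ]
  expect_equal(sd(sub$r43mc) / mean(sub$r43mc), cv43, tolerance = 0.05)
  expect_equal(sd(sub$r53mc) / mean(sub$r53mc), cv53, tolerance = 0.05)
  expect_equal(cor(sub$r43mc, sub$r53mc), 0.49, tolerance = 0.05)
  # cross-family independence: MC and MP ratios share no bone
  expect_lt(abs(cor(ratios$r43mc, ratios$r53mp)), 0.05)
})

test_that("reference cohort matches pooled printed moments and age structure", {
  fx <- default_reference_fixture()
  ratios <- fx$ratios
  expect_equal(mean(ratios$r43mc), 0.889, tolerance = 0.002 / 0.889)
  expect_equal(sd(ratios$r43mc), 0.019, tolerance = 0.003 / 0.019)
  expect_equal(mean(ratios$r53mc), 0.822, tolerance = 0.002 / 0.822)
  # group-6 dip in MC ratios, groups 5-6 step up in the MP ratio
  tab <- fx$table$groups
  m <- function(k) tab$mean[tab$ratio == k][1:6]
  expect_true(all(m("r43mc")[6] < m("r43mc")[1:5]))
  expect_true(all(m("r53mc")[6] < m("r53mc")[1:5]))
  expect_true(all(outer(m("r53mp")[5:6], m("r53mp")[1:4], `>`)))
})

test_that("ratios are invariant to the magnification range", {
  cfg1 <- generator_config(ref_n = 200, seed = 3,
                           magnification_range = c(1, 1))
  cfg2 <- generator_config(ref_n = 200, seed = 3,
                           magnification_range = c(0.5, 2.0))
  r1 <- compute_ratios(simulate_reference_cohort(cfg1)$lengths)
  r2 <- compute_ratios(simulate_reference_cohort(cfg2)$lengths)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("empty cohorts and invalid configs are handled before any draw", {
  empty <- simulate_reference_cohort(generator_config(ref_n = 0))
  expect_equal(nrow(empty$subjects), 0L)
  expect_error(generator_config(age_group_weights = rep(1, 6)),
               class = "phalanx_config_error")
  expect_error(generator_config(hand_scale_sd = -1),
               class = "phalanx_config_error")
  expect_error(generator_config(magnification_range = c(2, 1)),
               class = "phalanx_config_error")
})

test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(ref_n = 100, ts_n = 50, seed = 42)
  a <- simulate_reference_cohort(cfg)
  b <- simulate_reference_cohort(cfg)
  expect_identical(a, b)
  expect_identical(simulate_ts_cohort(cfg), simulate_ts_cohort(cfg))
})

test_that("mixture fit reproduces TS moments and flag prevalence", {
  fx <- default_reference_fixture()
  mix <- fit_ts_mixture(fx$table, 0.860, 0.050, 0.272)
  achieved <- attr(mix, "achieved")
  expect_equal(achieved[["mean"]], 0.860, tolerance = 0.02)
  expect_equal(achieved[["sd"]], 0.050, tolerance = 0.02)
  expect_equal(achieved[["flag_prev"]], 0.272, tolerance = 0.02)
  # Monte-Carlo corroboration of the analytic implied moments
  set.seed(1)
  n <- 1e5
  affected <- runif(n) < mix[["pi_affected"]]
  draws <- rnorm(n, mix[["center"]] - affected * mix[["delta_shift"]],
                 mix[["base_sd"]])
  expect_equal(mean(draws), achieved[["mean"]], tolerance = 1e-3)
  expect_equal(sd(draws), achieved[["sd"]], tolerance = 5e-3)
})

test_that("mixture fit admits the pi ~ 0 solution and rejects inconsistent targets", {
  fx <- default_reference_fixture()
  pooled <- fx$table$pooled
  ref_mean <- pooled$mean[pooled$ratio == "r43mc"]
  ref_sd <- pooled$sd[pooled$ratio == "r43mc"]
  mix <- fit_ts_mixture(fx$table, ref_mean, ref_sd, pnorm(-2))
  expect_lt(mix[["pi_affected"]] * mix[["delta_shift"]], 0.005)
  # prevalence target far above what mean/sd allow
  err <- tryCatch(
    fit_ts_mixture(fx$table, 0.95, 0.005, 0.9),
    error = function(e) e
  )
  expect_s3_class(err, "phalanx_mixture_error")
  expect_false(is.null(err$params))     # best-found parameters attached
  expect_false(is.null(err$achieved))
})

test_that("ratio-level TS cohort hits printed moments and correlations", {
  fx <- default_reference_fixture()
  cfg <- generator_config(ts_n = 1e4, seed = 5)
  cfg$ts_mixture <- fit_ts_mixture(fx$table, 0.860, 0.050, 0.272)
  ts <- simulate_ts_cohort(cfg, backend = "ratio_level")
  r <- ts$ratios
  expect_equal(mean(r$r43mc), 0.860, tolerance = 0.003 / 0.860)
  expect_equal(sd(r$r43mc), 0.050, tolerance = 0.1)
  expect_equal(cor(r$r43mc, r$r53mc), 0.478, tolerance = 0.03 / 0.478)
  expect_equal(cor(r$r43mc, r$r53mp), 0.26, tolerance = 0.05 / 0.26)
  # BDA3 tail of the printed 5:3 MP marginal
  expect_equal(mean(r$r53mp < 0.5), 0.136, tolerance = 0.015 / 0.136)
})

test_that("zero severity loading collapses TS correlations to reference values", {
  cfg <- generator_config(ts_n = 2e4, seed = 9,
                          ts_severity_loading = c(mc4 = 0, mc5 = 0, mp5 = 0))
  ts <- simulate_ts_cohort(cfg, backend = "length_level")
  r <- compute_ratios(ts$lengths)
  # shared-denominator value ~0.49, cross-family ~0
  expect_equal(cor(r$r43mc, r$r53mc), 0.49, tolerance = 0.1)
  expect_lt(abs(cor(r$r43mc, r$r53mp)), 0.05)
})

test_that("non-positive-definite implied correlations error with the matrix", {
  cfg <- generator_config(ts_n = 10,
                          ts_ratio_corr = c(r43_r53mc = 0.85,
                                            r43_r53mp = 0.85,
                                            r53mc_r53mp = -0.9))
  expect_error(simulate_ts_cohort(cfg, backend = "ratio_level"),
               class = "phalanx_corr_error")
})

test_that("TS metadata fields follow the configured probabilities", {
  cfg <- generator_config(ts_n = 5e3, seed = 13)
  ts <- simulate_ts_cohort(cfg)
  s <- ts$subjects
  expect_equal(mean(s$karyotype == "monosomy_45X"), 33 / 81, tolerance = 0.05)
  expect_equal(mean(s$gh_treated), 0.82, tolerance = 0.03)
  expect_equal(mean(s$shox_triangularization), 0.333, tolerance = 0.05)
  expect_equal(mean(s$shox_lucency), 0.235, tolerance = 0.05)
  expect_equal(mean(s$shox_pyramidalization), 0.136, tolerance = 0.05)
  expect_true(all(s$bone_age >= 3.0 & s$bone_age <= 17.9))
  expect_true(all(s$age_group == assign_age_group(s$bone_age)))
})

test_that("landmark emission is the exact inverse of measurement", {
  cfg <- generator_config(ref_n = 50, seed = 21)
  lengths <- simulate_reference_cohort(cfg)$lengths
  marks <- emit_landmarks(lengths, seed = 1)
  recovered <- measure_lengths(marks)
  recovered <- recovered[match(lengths$subject_id, recovered$subject_id), ]
  for (col in c("mc3", "mc4", "mc5", "mp3", "mp5")) {
    expect_equal(recovered[[col]], lengths[[col]], tolerance = 1e-9)
  }
  # orientation seed changes placements but not recovered lengths
  other <- measure_lengths(emit_landmarks(lengths, seed = 2))
  other <- other[match(lengths$subject_id, other$subject_id), ]
  expect_equal(other$mc3, lengths$mc3, tolerance = 1e-9)
  # single length example
  one <- emit_landmarks(tibble::tibble(subject_id = "S", mc3 = 50, mc4 = 40,
                                       mc5 = 35, mp3 = 20, mp5 = 12))
  d <- sqrt((one$head_x - one$base_x)^2 + (one$head_y - one$base_y)^2)
  expect_equal(d[one$bone == "MC3"], 50, tolerance = 1e-7)
})

test_that("generator config round-trips through its JSON sidecar", {
  cfg <- generator_config(ref_n = 123, ts_n = 45, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12,
               ignore_attr = TRUE)
  # JSON text representation of doubles may differ in the last ulp, so the
  # regenerated cohort agrees to numerical (not bitwise) identity
  expect_equal(simulate_reference_cohort(back)$lengths,
               simulate_reference_cohort(cfg)$lengths, tolerance = 1e-12)
})
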