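# Brute-force oracles for the ROC operations: exhaustive pair enumeration
# for the AUC and a full scan of all midpoint thresholds for Youden.
oracle_auc <- function(ref, ts) {
  pairs <- expand.grid(ts = ts, ref = ref)
  mean((pairs$ts < pairs$ref) + 0.5 * (pairs$ts == pairs$ref))
}

oracle_youden <- function(ref, ts) {
  v <- sort(unique(c(ref, ts)))
  cuts <- if (length(v) < 2) v else (v[-length(v)] + v[-1]) / 2
  j <- vapply(cuts, function(cc) mean(ts < cc) + mean(ref >= cc) - 1,
              numeric(1))
  list(cutoff = cuts[which(j == max(j))[1]], j = max(j))
}

test_that("empirical AUC equals exhaustive pairwise concordance", {
  expect_equal(empirical_auc(c(2, 3, 4), c(1, 2.5), ci = "none")$auc, 5 / 6)
  set.seed(17)
  for (i in 1:20) {
    ref <- round(rnorm(sample(2:50, 1)), sample(0:2, 1))  # ties likely
    ts <- round(rnorm(sample(2:50, 1), -0.5), sample(0:2, 1))
    expect_equal(empirical_auc(ref, ts, ci = "none")$auc,
                 oracle_auc(ref, ts))
  }
  # perfect separation and identical constants
  expect_equal(empirical_auc(c(5, 6, 7), c(1, 2), ci = "none")$auc, 1)
  expect_equal(empirical_auc(rep(1, 5), rep(1, 5), ci = "none")$auc, 0.5)
})

test_that("empirical AUC agrees with pROC and with the binormal closed form", {
  set.seed(23)
  ref <- rnorm(3000, 0.889, 0.019)
  ts <- rnorm(500, 0.860, 0.050)
  fit <- empirical_auc(ref, ts)
  cross <- as.numeric(pROC::auc(pROC::roc(
    response = factor(rep(c("r", "t"), c(3000, 500)), levels = c("r", "t")),
    predictor = c(ref, ts), direction = ">", quiet = TRUE)))
  expect_equal(fit$auc, cross, tolerance = 1e-12)
  # Monte-Carlo SE of AUC at these sizes is ~0.008; allow 3 SE
  expect_equal(fit$auc, binormal_auc(0.889, 0.019, 0.860, 0.050),
               tolerance = 0.025 / 0.7)
  expect_true(fit$auc_ci_low <= fit$auc && fit$auc <= fit$auc_ci_high)
})

test_that("null and transformed AUCs behave as concordance must", {
  set.seed(29)
  ref <- rnorm(5000)
  ts <- rnorm(5000)
  expect_equal(empirical_auc(ref, ts, ci = "none")$auc, 0.5,
               tolerance = 0.02 / 0.5)
  # invariance under a strictly decreasing transform of both samples:
  # lower-indicates-TS flips to higher-indicates-TS and back
  f <- function(x) -exp(x)
  auc1 <- empirical_auc(ref, ts, ci = "none")$auc
  auc2 <- empirical_auc(f(ref), f(ts), ci = "none")$auc
  expect_equal(auc1 + auc2, 1, tolerance = 1e-12)
})

test_that("binormal AUC reproduces printed-moment values", {
  expect_equal(binormal_auc(0.889, 0.019, 0.860, 0.050), 0.706,
               tolerance = 1e-3 / 0.706)
  expect_equal(binormal_auc(0.822, 0.022, 0.820, 0.040), 0.518,
               tolerance = 1e-3 / 0.518)
  expect_equal(binormal_auc(1, 0.5, 1, 0.3), 0.5)
  expect_error(binormal_auc(1, 0, 1, 0.3), class = "phalanx_roc_error")
})

test_that("Youden scan returns the smallest maximizing midpoint", {
  y <- youden_cutoff(c(0.90, 0.92), c(0.80, 0.86))
  expect_equal(y$cutoff, 0.88)
  expect_equal(y$j, 1)
  # identical samples: J = 0 everywhere, smallest midpoint returned
  y0 <- youden_cutoff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(y0$j, 0)
  expect_equal(y0$cutoff, 1.5)
  # oracle equivalence on random samples
  set.seed(37)
  for (i in 1:20) {
    ref <- round(rnorm(sample(3:50, 1), 1), 1)
    ts <- round(rnorm(sample(3:50, 1)), 1)
    got <- youden_cutoff(ref, ts)
    want <- oracle_youden(ref, ts)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$j, want$j)
    # maximality over every candidate midpoint
    expect_true(all(got$j >= vapply(
      candidate_cutoffs(c(ref, ts)),
      function(cc) mean(ts < cc) + mean(ref >= cc) - 1, numeric(1)) - 1e-12))
  }
})

test_that("operating point at a fixed cutoff, empirical and analytic", {
  ss <- sens_spec_at(0.876, c(0.889, 0.019), c(0.860, 0.050), analytic = TRUE)
  expect_equal(ss$sensitivity, 0.626, tolerance = 1e-2 / 0.626)
  expect_equal(ss$specificity, 0.753, tolerance = 1e-2 / 0.753)
  expect_equal(sens_spec_at(-1, c(0, 1, 2), c(3, 4))$sensitivity, 0)
  expect_equal(sens_spec_at(-1, c(0, 1, 2), c(3, 4))$specificity, 1)
  expect_equal(sens_spec_at(10, c(0, 1, 2), c(3, 4))$sensitivity, 1)
  expect_equal(sens_spec_at(10, c(0, 1, 2), c(3, 4))$specificity, 0)
  # the boundary value itself counts as negative (specific)
  at <- sens_spec_at(2, c(1, 2, 3), c(2, 0))
  expect_equal(at$sensitivity, 0.5)   # ts: only 0 < 2
  expect_equal(at$specificity, 2 / 3) # ref: 2 and 3 are >= 2
})

test_that("Pearson and partial correlation match their definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_lt(pearson_correlation(x, 2 * x + 1)$p_value, 1e-10)
  expect_error(pearson_correlation(x, rep(1, 5)),
               class = "phalanx_correlation_error")
  # partialling x out of itself leaves zero residual variance
  set.seed(41)
  covariate <- rnorm(50)
  expect_error(partial_correlation(covariate, rnorm(50), covariate),
               class = "phalanx_correlation_error")
  # x and y independent given the covariate: partial r ~ 0 even though the
  # marginal correlation is strong
  n <- 1e4
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  marginal <- pearson_correlation(x, y)$r
  partial <- partial_correlation(x, y, z)
  expect_gt(marginal, 0.4)
  expect_lt(abs(partial$r), 0.03)
  expect_equal(partial$adjusted_for, "covariate")
})

test_that("one-way ANOVA with Scheffé post-hoc behaves correctly", {
  # identical groups
  df <- data.frame(g = rep(1:3, each = 5), v = rep(c(1, 2, 3, 4, 5), 3))
  fit <- anova_scheffe(df, v, g)
  expect_equal(fit$f_statistic, 0)
  expect_true(all(tidy(fit)$p_value == 1))
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(43)
  df2 <- data.frame(g = rep(1:2, each = 20), v = rnorm(40, rep(c(0, 1), each = 20)))
  fit2 <- anova_scheffe(df2, v, g)
  t2 <- two_sample_t(df2$v[df2$g == 1], df2$v[df2$g == 2])$statistic^2
  expect_equal(fit2$f_statistic, t2, tolerance = 1e-10)
  # Scheffé is conservative vs the unadjusted pairwise contrast
  df3 <- data.frame(g = rep(1:4, each = 10), v = rnorm(40, rep(1:4 / 4, each = 10)))
  fit3 <- anova_scheffe(df3, v, g)
  k <- 4; N <- 40
  msw <- with(df3, sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (N - k))
  unadjusted <- pf(tidy(fit3)$diff^2 / (msw * (2 / 10)), 1, N - k,
                   lower.tail = FALSE)
  expect_true(all(tidy(fit3)$p_value >= unadjusted - 1e-12))
})

test_that("a 2-SD group-6 dip is detected against every other group", {
  set.seed(47)
  groups <- rep(1:6, each = 200)
  v <- rnorm(1200, ifelse(groups == 6, -2, 0), 1)
  fit <- anova_scheffe(data.frame(g = groups, v = v), v, g)
  six <- tidy(fit)[tidy(fit)$group1 == "6" | tidy(fit)$group2 == "6", ]
  expect_equal(nrow(six), 5L)
  expect_true(all(six$p_value < 0.001))
})

test_that("two-sample t-test variants and degenerate cases", {
  x <- c(1, 2, 3, 4)
  same <- two_sample_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- two_sample_t(rnorm(100), rnorm(100) + 50)
  expect_lt(shifted$p_value, 1e-10)
  expect_equal(two_sample_t(rep(1, 5), rep(1, 5))$p_value, 1)
  # student matches stats::t.test with pooled variance
  set.seed(51)
  a <- rnorm(30); b <- rnorm(25, 0.3)
  expect_equal(two_sample_t(a, b, "student")$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(a, b, "welch")$p_value, t.test(a, b)$p.value)
})

test_that("t-test holds its nominal type-I error under the null", {
  set.seed(53)
  rejections <- mean(replicate(2000, {
    two_sample_t(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_equal(rejections, 0.05, tolerance = 0.02 / 0.05)
})
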