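#' One-way ANOVA with Scheffé post-hoc comparisons
#'
#' Compares a ratio across bone-age groups. The omnibus F comes from
#' [stats::aov()]; each pairwise Scheffé p-value refers
#' \eqn{F_{pair} = \Delta^2 / (MSW (1/n_i + 1/n_j)(k-1))} to the
#' F(k-1, N-k) distribution, which is conservative relative to the
#' unadjusted pairwise contrast. The degenerate case of zero within-group
#' variance everywhere is handled explicitly (p = 0 for unequal means,
#' p = 1 otherwise).
#'
#' @param data A data frame.
#' @param value Column with the ratio values (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @return Object of class `phalanx_anova` with elements `f_statistic`,
#'   `df_between`, `df_within`, `p_value`, `group_means` and `pairwise`
#'   (tibble `group1, group2, diff, f, p_value`).
#' @examples
#' df <- data.frame(g = rep(letters[1:3], each = 10), v = rnorm(30))
#' anova_scheffe(df, v, g)
#' @export
anova_scheffe <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  n_i <- table(g)
  if (k < 2L || any(n_i < 2L)) {
    abort_phalanx("ANOVA requires >= 2 groups with n >= 2 each",
                  class = "phalanx_anova_error")
  }
  N <- length(v)
  fit <- stats::aov(v ~ g)
  tab <- summary(fit)[[1L]]
  msw <- tab["Residuals", "Mean Sq"]
  f_stat <- tab[1L, "F value"]
  p_omni <- tab[1L, "Pr(>F)"]
  means <- tapply(v, g, mean)

  pairs <- utils::combn(levels(g), 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    diff <- means[[i]] - means[[j]]
    denom <- msw * (1 / n_i[[i]] + 1 / n_i[[j]]) * (k - 1)
    if (denom == 0) {          # zero within-group variance everywhere
      p <- if (diff == 0) 1 else 0
      f_pair <- if (diff == 0) 0 else Inf
    } else {
      f_pair <- diff^2 / denom
      p <- stats::pf(f_pair, k - 1, N - k, lower.tail = FALSE)
    }
    tibble::tibble(group1 = i, group2 = j, diff = diff, f = f_pair,
                   p_value = p)
  })
  if (msw == 0) {
    f_stat <- if (all(pairwise$diff == 0)) 0 else Inf
    p_omni <- if (all(pairwise$diff == 0)) 1 else 0
  }
  structure(
    list(f_statistic = f_stat, df_between = k - 1L, df_within = N - k,
         p_value = p_omni,
         group_means = tibble::tibble(group = names(means),
                                      n = as.integer(n_i),
                                      mean = as.numeric(means)),
         pairwise = pairwise),
    class = "phalanx_anova"
  )
}

#' @export
print.phalanx_anova <- function(x, ...) {
  cat(sprintf("<phalanx_anova: F(%d, %d) = %.3f, p = %.3g>\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn anova_scheffe `tidy()` returns the Scheffé pairwise table.
#' @param x A `phalanx_anova`.
#' @param ... Unused.
#' @export
tidy.phalanx_anova <- function(x, ...) x$pairwise

#' @describeIn anova_scheffe `glance()` returns the omnibus row.
#' @export
glance.phalanx_anova <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value)
}

#' Two-sample t-test
#'
#' Student (pooled-variance, the default) or Welch, two-sided. The
#' degenerate zero-variance case returns t = 0, p = 1 for equal means and
#' p = 0 otherwise instead of erroring.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return One-row tibble `statistic, df, p_value, mean_x, mean_y, variant`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort_phalanx("each sample needs n >= 2", class = "phalanx_ttest_error")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    equal <- mean(x) == mean(y)
    return(tibble::tibble(statistic = if (equal) 0 else Inf,
                          df = NA_real_, p_value = if (equal) 1 else 0,
                          mean_x = mean(x), mean_y = mean(y),
                          variant = variant))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 mean_x = mean(x), mean_y = mean(y), variant = variant)
}
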