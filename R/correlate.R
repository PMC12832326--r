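#' Pearson correlation
#'
#' Thin broom-style wrapper around [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite,
#'   non-degenerate.
#' @return One-row tibble `r, p_value, n, adjusted_for`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    abort_phalanx("Pearson correlation requires n >= 3",
                  class = "phalanx_correlation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_phalanx("correlation undefined: zero variance",
                  class = "phalanx_correlation_error")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value, n = n,
                 adjusted_for = NA_character_)
}

#' Age-adjusted (partial) correlation
#'
#' Pearson correlation of the residuals from simple linear regressions of
#' `x` and `y` on the covariate (equivalently, the first-order partial
#' correlation); the p-value uses a t reference distribution with n - 3
#' degrees of freedom. Used for associations "after adjusting for bone age".
#'
#' @param x,y Numeric vectors, n >= 4.
#' @param covariate Numeric vector to partial out (e.g. bone age).
#' @param covariate_name Label recorded in the result.
#' @return One-row tibble `r, p_value, n, adjusted_for`.
#' @export
partial_correlation <- function(x, y, covariate,
                                covariate_name = "covariate") {
  stopifnot(length(x) == length(y), length(x) == length(covariate))
  ok <- is.finite(x) & is.finite(y) & is.finite(covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  if (n < 4L) {
    abort_phalanx("partial correlation requires n >= 4",
                  class = "phalanx_correlation_error")
  }
  rx <- stats::residuals(stats::lm(x ~ covariate))
  ry <- stats::residuals(stats::lm(y ~ covariate))
  if (stats::sd(rx) < 1e-12 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-12 * max(stats::sd(y), 1)) {
    abort_phalanx("partial correlation undefined: zero residual variance",
                  class = "phalanx_correlation_error")
  }
  r <- stats::cor(rx, ry)
  t_stat <- r * sqrt((n - 3) / (1 - r^2))
  tibble::tibble(r = r, p_value = 2 * stats::pt(-abs(t_stat), df = n - 3),
                 n = n, adjusted_for = covariate_name)
}
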