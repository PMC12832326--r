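#' Solve per-bone log-noise SDs from target ratio CVs and correlation
#'
#' Under the multiplicative bone-length model, a subject's 4:3 MC and 5:3 MC
#' ratios share the 3rd-metacarpal denominator, so denominator noise induces a
#' positive correlation between them. In the small-noise regime the moment
#' system is
#' \deqn{sd3^2 + sd4^2 = cv_{43}^2,\quad sd3^2 + sd5^2 = cv_{53}^2,\quad
#'       sd3^2 = \rho\, cv_{43}\, cv_{53},}
#' which this function solves in closed form for the per-bone log-scale noise
#' SDs of MC3, MC4 and MC5.
#'
#' @param cv_43,cv_53 Target coefficients of variation of the 4:3 MC and
#'   5:3 MC ratios (unitless, > 0).
#' @param target_corr Target Pearson correlation between the two ratios, in
#'   (0, 1). Must satisfy `target_corr * cv_43 * cv_53 < min(cv_43, cv_53)^2`,
#'   otherwise a solved variance is non-positive and the system is infeasible.
#' @return Named numeric vector `c(sd3, sd4, sd5)` of log-scale noise SDs.
#' @examples
#' calibrate_reference_noise(0.019 / 0.889, 0.022 / 0.822, 0.49)
#' @export
calibrate_reference_noise <- function(cv_43, cv_53, target_corr) {
  stopifnot(is.numeric(cv_43), is.numeric(cv_53), is.numeric(target_corr))
  if (cv_43 <= 0 || cv_53 <= 0) {
    abort_phalanx("cv_43 and cv_53 must be strictly positive",
                  class = "phalanx_infeasible_error")
  }
  if (target_corr < 0 || target_corr >= 1) {
    abort_phalanx("target_corr must lie in [0, 1)",
                  class = "phalanx_infeasible_error")
  }
  s3sq <- target_corr * cv_43 * cv_53
  s4sq <- cv_43^2 - s3sq
  s5sq <- cv_53^2 - s3sq
  if (s4sq <= 0 && target_corr > 0) {
    abort_phalanx(
      sprintf("infeasible: solved sd4^2 = cv_43^2 - corr*cv_43*cv_53 = %.3g <= 0",
              s4sq),
      class = "phalanx_infeasible_error"
    )
  }
  if (s5sq <= 0 && target_corr > 0) {
    abort_phalanx(
      sprintf("infeasible: solved sd5^2 = cv_53^2 - corr*cv_43*cv_53 = %.3g <= 0",
              s5sq),
      class = "phalanx_infeasible_error"
    )
  }
  c(sd3 = sqrt(s3sq), sd4 = sqrt(max(s4sq, 0)), sd5 = sqrt(max(s5sq, 0)))
}

# ---- two-component normal mixture for the TS 4:3 MC marginal -----------------

# A single normal with the TS pooled moments (0.860 +/- 0.050) would put ~43%
# of subjects below the age-matched -2 SD threshold, far above the observed
# prevalence. A two-component mixture (unaffected component centred at the
# reference mean, affected component shifted down by delta_shift, common
# base_sd) can reconcile pooled moments with flag prevalence.

mixture_pdf <- function(x, mix) {
  (1 - mix[["pi_affected"]]) * stats::dnorm(x, mix[["center"]], mix[["base_sd"]]) +
    mix[["pi_affected"]] * stats::dnorm(x, mix[["center"]] - mix[["delta_shift"]],
                                        mix[["base_sd"]])
}

mixture_cdf <- function(q, mix) {
  (1 - mix[["pi_affected"]]) * stats::pnorm(q, mix[["center"]], mix[["base_sd"]]) +
    mix[["pi_affected"]] * stats::pnorm(q, mix[["center"]] - mix[["delta_shift"]],
                                        mix[["base_sd"]])
}

# Quantile via monotone interpolation of the CDF on a fine grid; accurate to
# well below the generator's Monte-Carlo noise.
mixture_quantile <- function(p, mix) {
  lo <- mix[["center"]] - mix[["delta_shift"]] - 8 * mix[["base_sd"]]
  hi <- mix[["center"]] + 8 * mix[["base_sd"]]
  grid <- seq(lo, hi, length.out = 8192L)
  stats::approx(mixture_cdf(grid, mix), grid, xout = p,
                ties = "ordered", rule = 2)$y
}

mixture_moments <- function(mix) {
  pi_a <- mix[["pi_affected"]]
  mean <- mix[["center"]] - pi_a * mix[["delta_shift"]]
  var <- mix[["base_sd"]]^2 + pi_a * (1 - pi_a) * mix[["delta_shift"]]^2
  c(mean = mean, sd = sqrt(var))
}

# Pearson attenuation of a Gaussian copula margin mapped through the mixture
# quantile transform: corr(Q_mix(Phi(Z)), Z). Computed by quadrature on a
# dense grid; used to pre-compensate latent correlations in the TS generator.
mixture_attenuation <- function(mix) {
  z <- seq(-8, 8, length.out = 16384L)
  w <- stats::dnorm(z)
  f <- mixture_quantile(stats::pnorm(z), mix)
  m <- sum(f * w) / sum(w)
  s <- sqrt(sum((f - m)^2 * w) / sum(w))
  sum(z * (f - m) * w) / sum(w) / s
}

# Probability that a TS subject drawn from the mixture falls below the
# age-matched (mean_g - k*sd_g) threshold, averaged over age-group occupancy.
mixture_flag_prevalence <- function(mix, thresholds, weights) {
  pi_a <- mix[["pi_affected"]]
  per_group <- (1 - pi_a) *
    stats::pnorm((thresholds - mix[["center"]]) / mix[["base_sd"]]) +
    pi_a * stats::pnorm((thresholds - mix[["center"]] + mix[["delta_shift"]]) /
                          mix[["base_sd"]])
  sum(weights * per_group)
}

#' Fit the TS 4:3 MC two-component mixture to pooled moments and flag prevalence
#'
#' Finds `(pi_affected, delta_shift, base_sd)` such that the implied cohort
#' mean, SD and fraction below the age-matched -2 SD threshold (averaged over
#' the TS age-group occupancy) match the supplied targets. The implied
#' quantities are closed-form in the mixture parameters; fitting minimises the
#' summed squared relative error with Nelder-Mead from several starts.
#'
#' @param reference A `phalanx_reference` table providing the age-matched
#'   group means/SDs of the 4:3 MC ratio (thresholds) and the pooled mean
#'   (centre of the unaffected component).
#' @param target_mean,target_sd Target pooled TS moments of the 4:3 MC ratio.
#' @param target_flag_prev Target fraction of TS subjects flagged below the
#'   age-matched -2 SD threshold, in (0, 1).
#' @param age_weights Occupancy weights of the six bone-age groups in the TS
#'   cohort; defaults to the occupancy implied by a uniform bone-age
#'   distribution on 3.0-17.9 years.
#' @param mc_sds Number of SDs below the group mean defining the threshold
#'   (default 2).
#' @param tol Maximum tolerated absolute relative error on any single target
#'   (default 0.02).
#' @return Named numeric vector `c(pi_affected, delta_shift, base_sd, center)`
#'   with the achieved targets in attribute `"achieved"`.
#' @export
fit_ts_mixture <- function(reference, target_mean, target_sd, target_flag_prev,
                           age_weights = NULL, mc_sds = 2, tol = 0.02) {
  stopifnot(inherits(reference, "phalanx_reference"))
  if (target_flag_prev <= 0 || target_flag_prev >= 1) {
    abort_phalanx("target_flag_prev must lie in (0, 1)",
                  class = "phalanx_mixture_error")
  }
  rows <- reference$groups[reference$groups$ratio == "r43mc", ]
  rows <- rows[order(rows$age_group), ]
  if (anyNA(rows$sd)) {
    abort_phalanx("reference table has groups without an available SD for r43mc",
                  class = "phalanx_reference_error")
  }
  thresholds <- rows$mean - mc_sds * rows$sd
  if (is.null(age_weights)) {
    widths <- pmax(pmin(AGE_BREAKS[-1], 17.9) - pmax(AGE_BREAKS[-7], 3.0), 0)
    age_weights <- widths / sum(widths)
  }
  center <- reference$pooled$mean[reference$pooled$ratio == "r43mc"]
  targets <- c(target_mean, target_sd, target_flag_prev)

  objective <- function(par) {
    mix <- c(pi_affected = stats::plogis(par[1]), delta_shift = exp(par[2]),
             base_sd = exp(par[3]), center = center)
    mm <- mixture_moments(mix)
    prev <- mixture_flag_prevalence(mix, thresholds, age_weights)
    sum(((c(mm[["mean"]], mm[["sd"]], prev) - targets) / targets)^2)
  }

  starts <- list(
    c(stats::qlogis(0.27), log(0.10), log(0.015)),
    c(stats::qlogis(0.05), log(0.05), log(target_sd)),
    c(stats::qlogis(0.5), log(2 * target_sd), log(target_sd / 2))
  )
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  mix <- c(pi_affected = stats::plogis(best$par[1]),
           delta_shift = exp(best$par[2]),
           base_sd = exp(best$par[3]),
           center = center)
  mm <- mixture_moments(mix)
  achieved <- c(mean = unname(mm[["mean"]]), sd = unname(mm[["sd"]]),
                flag_prev = mixture_flag_prevalence(mix, thresholds, age_weights))
  rel_err <- abs(achieved - targets) / targets
  if (any(rel_err > tol)) {
    abort_phalanx(
      sprintf(paste0("mixture fit did not reach all targets within %.0f%% ",
                     "relative error (worst %.1f%% on %s)"),
              100 * tol, 100 * max(rel_err), names(which.max(rel_err))),
      class = "phalanx_mixture_error",
      params = mix, achieved = achieved, targets = targets
    )
  }
  attr(mix, "achieved") <- achieved
  mix
}
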