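# ROC / Youden analysis of a ratio discriminating TS from reference.
# Orientation is fixed globally: LOWER ratios indicate TS, so AUC is the
# probability that a random TS subject has a smaller ratio than a random
# reference subject (ties counted 1/2).

#' Empirical AUC (Mann-Whitney concordance) with DeLong CI
#'
#' AUC is computed by the rank formula for the Mann-Whitney U statistic —
#' identical to exhaustive enumeration of (TS, reference) pairs with ties
#' counted 1/2 — oriented so lower ratios indicate TS. The 95% CI is DeLong's
#' (via pROC); on degenerate input (fewer than two distinct pooled values)
#' the CI collapses to the point estimate.
#'
#' @param reference_values Ratios of the reference cohort.
#' @param ts_values Ratios of the TS cohort.
#' @param ci `"delong"` (default) or `"none"`.
#' @return Object of class `phalanx_roc`: `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `n_ref`, `n_ts`, `orientation`, and the input samples (for plotting).
#' @examples
#' empirical_auc(c(2, 3, 4), c(1, 2.5))$auc  # 5/6
#' @export
empirical_auc <- function(reference_values, ts_values,
                          ci = c("delong", "none")) {
  ci <- match.arg(ci)
  stopifnot(length(reference_values) > 0, length(ts_values) > 0,
            all(is.finite(reference_values)), all(is.finite(ts_values)))
  n_ref <- length(reference_values)
  n_ts <- length(ts_values)
  pooled <- c(reference_values, ts_values)
  r <- rank(pooled)  # midranks handle ties as 1/2 concordance
  auc <- (sum(r[seq_len(n_ref)]) - n_ref * (n_ref + 1) / 2) / (n_ref * n_ts)
  ci_bounds <- c(auc, auc)
  if (ci == "delong" && length(unique(pooled)) >= 2L) {
    roc_obj <- pROC::roc(
      response = factor(rep(c("ref", "ts"), c(n_ref, n_ts)),
                        levels = c("ref", "ts")),
      predictor = pooled, direction = ">", quiet = TRUE
    )
    delong <- as.numeric(pROC::ci.auc(roc_obj, method = "delong"))
    ci_bounds <- pmin(pmax(delong[c(1, 3)], 0), 1)
  }
  structure(
    list(auc = auc, auc_ci_low = min(ci_bounds[1], auc),
         auc_ci_high = max(ci_bounds[2], auc),
         n_ref = n_ref, n_ts = n_ts,
         orientation = "lower ratio indicates TS",
         reference_values = reference_values, ts_values = ts_values),
    class = "phalanx_roc"
  )
}

#' @export
print.phalanx_roc <- function(x, ...) {
  cat(sprintf("<phalanx_roc: AUC %.3f (95%% CI %.3f-%.3f), n_ref %d, n_ts %d>\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$n_ref, x$n_ts))
  cat(sprintf("  orientation: %s\n", x$orientation))
  if (!is.null(x$youden)) {
    cat(sprintf("  Youden cutoff %.4f (J = %.3f, sens %.1f%%, spec %.1f%%)\n",
                x$youden$cutoff, x$youden$j, 100 * x$youden$sensitivity,
                100 * x$youden$specificity))
  }
  invisible(x)
}

#' @describeIn empirical_auc `glance()` one-row summary.
#' @param x A `phalanx_roc`.
#' @param ... Unused.
#' @export
glance.phalanx_roc <- function(x, ...) {
  out <- tibble::tibble(auc = x$auc, auc_ci_low = x$auc_ci_low,
                        auc_ci_high = x$auc_ci_high,
                        n_ref = x$n_ref, n_ts = x$n_ts)
  if (!is.null(x$youden)) out <- dplyr::bind_cols(out, x$youden)
  out
}

#' @describeIn empirical_auc `tidy()` sensitivity/specificity along the
#'   empirical curve (one row per candidate cutoff).
#' @export
tidy.phalanx_roc <- function(x, ...) {
  cuts <- candidate_cutoffs(c(x$reference_values, x$ts_values))
  purrr::map_dfr(cuts, function(cc) {
    ss <- sens_spec_at(cc, x$reference_values, x$ts_values)
    tibble::tibble(cutoff = cc, sensitivity = ss$sensitivity,
                   specificity = ss$specificity)
  })
}

#' Closed-form binormal AUC
#'
#' When both cohorts' ratios are normal, the AUC for the lower-ratio-
#' indicates-TS orientation is
#' \eqn{\Phi\big((\mu_{ref} - \mu_{ts}) / \sqrt{\sigma_{ref}^2 + \sigma_{ts}^2}\big)}.
#' Serves as an analytic oracle for [empirical_auc()] and reproduces AUCs
#' from printed cohort moments.
#'
#' @param mu_ref,sd_ref Reference cohort mean and SD.
#' @param mu_ts,sd_ts TS cohort mean and SD.
#' @return AUC in \[0, 1\].
#' @examples
#' binormal_auc(0.889, 0.019, 0.860, 0.050)
#' @export
binormal_auc <- function(mu_ref, sd_ref, mu_ts, sd_ts) {
  if (sd_ref <= 0 || sd_ts <= 0) {
    abort_phalanx("SDs must be strictly positive", class = "phalanx_roc_error")
  }
  stats::pnorm((mu_ref - mu_ts) / sqrt(sd_ref^2 + sd_ts^2))
}

candidate_cutoffs <- function(pooled) {
  v <- sort(unique(pooled))
  if (length(v) < 2L) return(v)
  (v[-length(v)] + v[-1L]) / 2
}

#' Youden-optimal cutoff
#'
#' Scans candidate cutoffs at midpoints between adjacent distinct pooled
#' values; J(c) = sens(c) + spec(c) - 1 with sens = fraction of TS values
#' strictly below c and spec = fraction of reference values at or above c.
#' Ties in J are broken deterministically by returning the smallest
#' maximizing cutoff.
#'
#' @inheritParams empirical_auc
#' @return One-row tibble `cutoff, j, sensitivity, specificity`.
#' @export
youden_cutoff <- function(reference_values, ts_values) {
  stopifnot(length(reference_values) > 0, length(ts_values) > 0)
  cuts <- candidate_cutoffs(c(reference_values, ts_values))
  sens <- vapply(cuts, function(cc) mean(ts_values < cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(reference_values >= cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]  # cuts ascending -> smallest maximizer
  tibble::tibble(cutoff = cuts[best], j = j[best],
                 sensitivity = sens[best], specificity = spec[best])
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Empirical mode counts `ts < cutoff` as sensitive and `ref >= cutoff` as
#' specific (the value at the cutoff itself counts as negative). Analytic
#' mode evaluates the normal-CDF counterparts from supplied `(mean, sd)`
#' pairs instead of samples.
#'
#' @param cutoff Ratio cutoff value.
#' @param reference Either a numeric sample or `c(mean, sd)` with
#'   `analytic = TRUE`.
#' @param ts Either a numeric sample or `c(mean, sd)` with `analytic = TRUE`.
#' @param analytic Use normal closed forms (default `FALSE`).
#' @return One-row tibble `cutoff, sensitivity, specificity`.
#' @examples
#' sens_spec_at(0.876, c(0.889, 0.019), c(0.860, 0.050), analytic = TRUE)
#' @export
sens_spec_at <- function(cutoff, reference, ts, analytic = FALSE) {
  stopifnot(is.finite(cutoff))
  if (analytic) {
    stopifnot(length(reference) == 2L, length(ts) == 2L,
              reference[2] > 0, ts[2] > 0)
    sens <- stats::pnorm((cutoff - ts[1]) / ts[2])
    spec <- 1 - stats::pnorm((cutoff - reference[1]) / reference[2])
  } else {
    sens <- mean(ts < cutoff)
    spec <- mean(reference >= cutoff)
  }
  tibble::tibble(cutoff = cutoff, sensitivity = unname(sens),
                 specificity = unname(spec))
}

#' Full ROC analysis of one ratio
#'
#' Bundles [empirical_auc()], [youden_cutoff()] and, when `cutoff` is given,
#' the operating point at that fixed cutoff.
#'
#' @inheritParams empirical_auc
#' @param cutoff Optional fixed cutoff to report an operating point at
#'   (e.g. 0.876 for the 4:3 MC ratio).
#' @return A `phalanx_roc` with `youden` (and `fixed_cutoff`) elements.
#' @export
roc_analysis <- function(reference_values, ts_values, cutoff = NULL,
                         ci = c("delong", "none")) {
  out <- empirical_auc(reference_values, ts_values, ci = match.arg(ci))
  out$youden <- youden_cutoff(reference_values, ts_values)
  if (!is.null(cutoff)) {
    out$fixed_cutoff <- sens_spec_at(cutoff, reference_values, ts_values)
  }
  out
}
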