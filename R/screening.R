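#' Age-matched z-score against the reference table
#'
#' `(value - mean_gk) / sd_gk` using the subject's bone-age group row; no
#' interpolation between groups and no silent pooled fallback — a group whose
#' SD is unavailable raises an error.
#'
#' @param value Ratio value(s).
#' @param ratio One of `"r43mc", "r53mc", "r53mp"`.
#' @param bone_age Bone age(s) in years (vectorized with `value`).
#' @param reference A `phalanx_reference`.
#' @return Numeric z-score(s) in SDS.
#' @export
ratio_zscore <- function(value, ratio, bone_age, reference) {
  stopifnot(inherits(reference, "phalanx_reference"))
  ratio <- match.arg(ratio, RATIO_COLS)
  group <- assign_age_group(bone_age)
  rows <- reference$groups[reference$groups$ratio == ratio, ]
  rows <- rows[order(rows$age_group), ]
  sd_g <- rows$sd[group]
  if (anyNA(sd_g)) {
    abort_phalanx(
      sprintf("reference SD unavailable for %s in age group(s) %s",
              ratio, paste(sort(unique(group[is.na(sd_g)])), collapse = ", ")),
      class = "phalanx_reference_error"
    )
  }
  unname((value - rows$mean[group]) / sd_g)
}

#' Screen a cohort for metacarpal sign and brachydactyly type A3
#'
#' Computes age-matched z-scores of the three ratios and the radiographic
#' flags: metacarpal sign when the 4:3 MC (or 5:3 MC) z-score is strictly
#' below `mc_sds` (default -2; a subject exactly at -2 is not flagged), and
#' BDA3 when the 5:3 MP ratio is strictly below `bda3_threshold` (default
#' 0.5). Flags are fully re-derivable from the stored z-scores and ratios.
#'
#' @param ratios Tibble `subject_id, r43mc, r53mc, r53mp`.
#' @param metadata Tibble with `subject_id` and `bone_age`.
#' @param reference A `phalanx_reference`.
#' @param mc_sds Metacarpal-sign z threshold in SDS (default -2).
#' @param bda3_threshold BDA3 ratio threshold (default 0.5).
#' @return Tibble `subject_id, group_used, z43mc, z53mc, z53mp,
#'   flag_mc43_short, flag_mc53_short, flag_bda3`.
#' @export
screen_cohort <- function(ratios, metadata, reference,
                          mc_sds = -2, bda3_threshold = 0.5) {
  check_columns(ratios, c("subject_id", RATIO_COLS), "ratios table")
  check_columns(metadata, c("subject_id", "bone_age"), "metadata table")
  joined <- dplyr::inner_join(ratios, metadata[c("subject_id", "bone_age")],
                              by = "subject_id")
  if (nrow(joined) < nrow(ratios)) {
    abort_phalanx(
      sprintf("%d subject(s) have no metadata row",
              nrow(ratios) - nrow(joined)),
      class = "phalanx_screening_error"
    )
  }
  group <- assign_age_group(joined$bone_age)
  z <- lapply(RATIO_COLS, function(k) {
    ratio_zscore(joined[[k]], k, joined$bone_age, reference)
  })
  names(z) <- paste0("z", sub("^r", "", RATIO_COLS))
  tibble::tibble(
    subject_id = joined$subject_id,
    group_used = group,
    z43mc = z$z43mc,
    z53mc = z$z53mc,
    z53mp = z$z53mp,
    flag_mc43_short = z$z43mc < mc_sds,
    flag_mc53_short = z$z53mc < mc_sds,
    flag_bda3 = joined$r53mp < bda3_threshold
  )
}

#' Classify a single subject
#'
#' Convenience wrapper around [screen_cohort()] for one subject.
#'
#' @param r43mc,r53mc,r53mp The subject's three ratios.
#' @param bone_age Bone age in years.
#' @param reference A `phalanx_reference`.
#' @inheritParams screen_cohort
#' @return One-row screening tibble (see [screen_cohort()]).
#' @export
classify_subject <- function(r43mc, r53mc, r53mp, bone_age, reference,
                             mc_sds = -2, bda3_threshold = 0.5) {
  screen_cohort(
    tibble::tibble(subject_id = "subject", r43mc = r43mc, r53mc = r53mc,
                   r53mp = r53mp),
    tibble::tibble(subject_id = "subject", bone_age = bone_age),
    reference, mc_sds = mc_sds, bda3_threshold = bda3_threshold
  )
}

#' Compare two proportions (chi-square or Fisher)
#'
#' Pearson chi-square without continuity correction when every expected count
#' of the 2x2 table is at least 5, otherwise Fisher's exact test (two-sided)
#' — the standard reading of "as appropriate". `method` can force either
#' test. Degenerate tables (a zero margin, i.e. no events or all events in
#' both cohorts) carry no evidence of a difference and return p = 1.
#'
#' @param x1,n1 Events and trials in cohort 1.
#' @param x2,n2 Events and trials in cohort 2.
#' @param method `"auto"` (default), `"chisq"` or `"fisher"`.
#' @return One-row tibble `method, statistic, p_value`.
#' @export
compare_proportions <- function(x1, n1, x2, n2,
                                method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(method = "degenerate", statistic = 0, p_value = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (all(expected >= 5)) "chisq" else "fisher"
  }
  if (method == "chisq") {
    # the auto rule already enforces expected counts >= 5; a forced chisq on
    # smaller counts is the caller's explicit choice, so the approximation
    # note is suppressed
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(method = "chisq", statistic = unname(ht$statistic),
                   p_value = ht$p.value)
  } else {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    tibble::tibble(method = "fisher", statistic = NA_real_,
                   p_value = ht$p.value)
  }
}

#' Cohort prevalence of radiographic flags and SHOX signs
#'
#' Proportions of the screening flags, and of the three SHOX wrist-sign
#' annotations if metadata is supplied (tri-state booleans: unknown values
#' are excluded from that sign's denominator; a denominator that empties out
#' is reported as not computable, not as zero). If a comparison cohort is
#' given, each flag is tested with [compare_proportions()].
#'
#' @param results Screening tibble from [screen_cohort()].
#' @param shox_annotations Optional metadata tibble with the three
#'   `shox_*` columns.
#' @param compare_to Optional list with the same shape
#'   (`results`, `shox_annotations`) for a second cohort.
#' @return Tibble `measure, count, n, proportion` plus
#'   `method, statistic, p_value` when comparing.
#' @export
cohort_prevalence <- function(results, shox_annotations = NULL,
                              compare_to = NULL) {
  if (nrow(results) == 0L) {
    abort_phalanx("cannot summarise an empty cohort",
                  class = "phalanx_screening_error")
  }
  tally_one <- function(res, shox) {
    flags <- c("flag_mc43_short", "flag_mc53_short", "flag_bda3")
    out <- purrr::map_dfr(flags, function(f) {
      tibble::tibble(measure = f, count = sum(res[[f]]), n = nrow(res))
    })
    if (!is.null(shox)) {
      signs <- c("shox_triangularization", "shox_lucency",
                 "shox_pyramidalization")
      check_columns(shox, signs, "shox annotations")
      out <- dplyr::bind_rows(out, purrr::map_dfr(signs, function(s) {
        known <- !is.na(shox[[s]])
        tibble::tibble(measure = s, count = sum(shox[[s]][known]),
                       n = sum(known))
      }))
    }
    out$proportion <- ifelse(out$n > 0, out$count / out$n, NA_real_)
    out
  }
  summary <- tally_one(results, shox_annotations)
  if (is.null(compare_to)) {
    return(summary)
  }
  other <- tally_one(compare_to$results, compare_to$shox_annotations)
  tests <- purrr::map_dfr(seq_len(nrow(summary)), function(i) {
    j <- match(summary$measure[i], other$measure)
    if (is.na(j) || summary$n[i] == 0 || other$n[j] == 0) {
      return(tibble::tibble(method = "not_computable", statistic = NA_real_,
                            p_value = NA_real_))
    }
    compare_proportions(summary$count[i], summary$n[i],
                        other$count[j], other$n[j])
  })
  dplyr::bind_cols(summary, tests)
}
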