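#' Synthetic-cohort generator configuration
#'
#' Builds and validates the full set of distributional parameters for the
#' reference and Turner syndrome (TS) cohort generators. Defaults are
#' calibrated once to the cohort summary statistics the generators emulate:
#' pooled reference ratios 0.889 +/- 0.019 (4:3 MC) and 0.822 +/- 0.022
#' (5:3 MC) with inter-ratio correlation 0.49; TS ratios 0.860 +/- 0.050,
#' 0.820 +/- 0.040 and 0.600 +/- 0.090 with correlations 0.478 and 0.26; a
#' group-6 dip in both MC ratios and a groups-5/6 step up in the 5:3 MP ratio.
#'
#' Bone lengths follow a multiplicative log-normal model: per-image
#' magnification x subject hand scale x age-group bone proportion x per-bone
#' log-normal noise. Ratios cancel magnification and hand scale exactly, so
#' ratio moments depend only on the proportions and the per-bone noise SDs,
#' which makes calibration tractable (see [calibrate_reference_noise()]).
#'
#' @param ref_n,ts_n Cohort sizes (defaults 4438 reference, 81 TS).
#' @param age_group_weights Six nonnegative occupancy weights for the
#'   reference bone-age groups, summing to 1.
#' @param ref_ratio_group_means 6 x 3 matrix of target ratio means per age
#'   group (columns r43mc, r53mc, r53mp). Defaults encode the pooled targets
#'   with the group-6 metacarpal dip and the late-puberty 5:3 MP step.
#' @param log_noise_sd Named vector `sd3, sd4, sd5, sdMP3, sdMP5` of per-bone
#'   log-scale noise SDs; defaults from [calibrate_reference_noise()] for the
#'   metacarpals and an even split of the 5:3 MP CV for the phalanges.
#' @param hand_scale_sd SD of the shared log hand-size factor.
#' @param magnification_range Min/max of the uniform per-image scale factor.
#' @param mc_proportions,mp_proportions Optional 6 x 3 / 6 x 2 matrices of
#'   expected bone-length proportions (columns mc3, mc4, mc5 / mp3, mp5)
#'   relative to the unit hand scale; derived from `ref_ratio_group_means`
#'   and `log_noise_sd` when `NULL`.
#' @param ts_ratio_means,ts_ratio_sds TS pooled ratio means and SDs
#'   (r43mc, r53mc, r53mp).
#' @param ts_ratio_corr Target TS Pearson correlations
#'   `c(r43_r53mc, r43_r53mp, r53mc_r53mp)`; the third pair is not reported
#'   and defaults to 0.2.
#' @param ts_mixture Two-component mixture for the TS 4:3 MC marginal,
#'   `c(pi_affected, delta_shift, base_sd, center)`; defaults are
#'   moment-matched to the pooled TS targets and a 27.2% flag prevalence,
#'   and are typically refit against a concrete reference table with
#'   [fit_ts_mixture()].
#' @param ts_severity_loading Named multiplicative deficits `mc4, mc5, mp5`
#'   coupling a shared latent severity to the affected bones in the
#'   length-level TS backend.
#' @param shox_sign_probs Prevalences of the three SHOX-deficiency wrist
#'   signs (triangularization, lucency, pyramidalization) consumed as
#'   annotations.
#' @param monosomy_prob Probability of a 45,X karyotype (default 33/81).
#' @param gh_prob Probability of growth-hormone treatment (default 0.82).
#' @param ts_age_range Bone-age range of the TS cohort (default 3.0-17.9).
#' @param hand_scale_base Median hand scale in pixels (MC3 at unit
#'   proportion).
#' @param seed Integer random seed; all generator randomness derives from it.
#' @return A validated list of class `phalanx_config`.
#' @export
generator_config <- function(ref_n = 4438L,
                             ts_n = 81L,
                             age_group_weights = rep(1 / 6, 6),
                             ref_ratio_group_means = NULL,
                             log_noise_sd = NULL,
                             hand_scale_sd = 0.12,
                             magnification_range = c(0.8, 1.25),
                             mc_proportions = NULL,
                             mp_proportions = NULL,
                             ts_ratio_means = c(r43mc = 0.860, r53mc = 0.820,
                                                r53mp = 0.600),
                             ts_ratio_sds = c(r43mc = 0.050, r53mc = 0.040,
                                              r53mp = 0.090),
                             ts_ratio_corr = c(r43_r53mc = 0.478,
                                               r43_r53mp = 0.26,
                                               r53mc_r53mp = 0.2),
                             ts_mixture = c(pi_affected = 0.268,
                                            delta_shift = 0.108,
                                            base_sd = 0.0140,
                                            center = 0.889),
                             ts_severity_loading = c(mc4 = 0.035, mc5 = 0.012,
                                                     mp5 = 0.055),
                             shox_sign_probs = c(triangularization = 0.333,
                                                 lucency = 0.235,
                                                 pyramidalization = 0.136),
                             monosomy_prob = 33 / 81,
                             gh_prob = 0.82,
                             ts_age_range = c(3.0, 17.9),
                             hand_scale_base = 55,
                             seed = 1L) {
  if (is.null(log_noise_sd)) {
    mc <- calibrate_reference_noise(0.019 / 0.889, 0.022 / 0.822, 0.49)
    # 5:3 MP: pooled SD ~0.055 at pooled mean 0.615, split evenly across
    # numerator and denominator phalanges (no printed correlation constrains
    # the split; MP ratios share no bone with MC ratios, so cross-family
    # correlations vanish by construction).
    cv_mp <- 0.055 / 0.615
    log_noise_sd <- c(mc, sdMP3 = cv_mp / sqrt(2), sdMP5 = cv_mp / sqrt(2))
  }
  if (is.null(ref_ratio_group_means)) {
    # Group-6 dip sizes chosen so pooled means under uniform occupancy hit
    # the pooled targets exactly while the dip is large relative to the
    # between-group standard error (pairwise significance at cohort scale).
    d43 <- 0.008
    d53 <- 0.009
    ref_ratio_group_means <- cbind(
      r43mc = c(rep(0.889 + d43 / 6, 5), 0.889 + d43 / 6 - d43),
      r53mc = c(rep(0.822 + d53 / 6, 5), 0.822 + d53 / 6 - d53),
      r53mp = c(rep(0.605, 4), 0.635, 0.635)
    )
  }

  config <- list(
    ref_n = as.integer(ref_n), ts_n = as.integer(ts_n),
    age_group_weights = age_group_weights,
    ref_ratio_group_means = ref_ratio_group_means,
    log_noise_sd = log_noise_sd,
    hand_scale_sd = hand_scale_sd,
    magnification_range = magnification_range,
    mc_proportions = mc_proportions,
    mp_proportions = mp_proportions,
    ts_ratio_means = ts_ratio_means,
    ts_ratio_sds = ts_ratio_sds,
    ts_ratio_corr = ts_ratio_corr,
    ts_mixture = ts_mixture,
    ts_severity_loading = ts_severity_loading,
    shox_sign_probs = shox_sign_probs,
    monosomy_prob = monosomy_prob,
    gh_prob = gh_prob,
    ts_age_range = ts_age_range,
    hand_scale_base = hand_scale_base,
    seed = as.integer(seed)
  )
  if (is.null(config$mc_proportions) || is.null(config$mp_proportions)) {
    props <- derive_bone_proportions(config$ref_ratio_group_means,
                                     config$log_noise_sd)
    config$mc_proportions <- config$mc_proportions %||% props$mc
    config$mp_proportions <- config$mp_proportions %||% props$mp
  }
  validate_config(config)
}

# Expected bone proportions that make the log-normal ratio means equal the
# target group means: E[(p_num/p_den) exp(eps_num - eps_den)] =
# (p_num/p_den) exp((sd_num^2 + sd_den^2)/2), hence the exp(-.) correction.
derive_bone_proportions <- function(group_means, noise) {
  mc3 <- c(0.72, 0.82, 0.90, 1.00, 1.06, 1.10)   # age growth of the hand
  mp3 <- 0.52 * mc3
  corr43 <- exp(-(noise[["sd3"]]^2 + noise[["sd4"]]^2) / 2)
  corr53 <- exp(-(noise[["sd3"]]^2 + noise[["sd5"]]^2) / 2)
  corr53mp <- exp(-(noise[["sdMP3"]]^2 + noise[["sdMP5"]]^2) / 2)
  list(
    mc = cbind(mc3 = mc3,
               mc4 = mc3 * group_means[, "r43mc"] * corr43,
               mc5 = mc3 * group_means[, "r53mc"] * corr53),
    mp = cbind(mp3 = mp3,
               mp5 = mp3 * group_means[, "r53mp"] * corr53mp)
  )
}

validate_config <- function(config) {
  w <- config$age_group_weights
  if (length(w) != 6L || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort_phalanx("age_group_weights must be 6 nonnegative weights summing to 1",
                  class = "phalanx_config_error")
  }
  sds <- c(config$log_noise_sd, config$hand_scale_sd, config$ts_ratio_sds,
           config$ts_mixture[["base_sd"]])
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    abort_phalanx("all SDs and scale factors must be strictly positive",
                  class = "phalanx_config_error")
  }
  probs <- c(config$shox_sign_probs, config$monosomy_prob, config$gh_prob,
             config$ts_mixture[["pi_affected"]])
  if (any(probs < 0 | probs > 1)) {
    abort_phalanx("probabilities (including pi_affected) must lie in [0, 1]",
                  class = "phalanx_config_error")
  }
  mag <- config$magnification_range
  if (length(mag) != 2L || any(mag <= 0) || mag[1] > mag[2]) {
    abort_phalanx("magnification_range must be 0 < min <= max",
                  class = "phalanx_config_error")
  }
  if (config$ref_n < 0 || config$ts_n < 0) {
    abort_phalanx("cohort sizes must be nonnegative",
                  class = "phalanx_config_error")
  }
  if (any(config$mc_proportions <= 0) || any(config$mp_proportions <= 0)) {
    abort_phalanx("bone proportions must be strictly positive",
                  class = "phalanx_config_error")
  }
  structure(config, class = "phalanx_config")
}

#' @export
print.phalanx_config <- function(x, ...) {
  cat("<phalanx_config>\n")
  cat(sprintf("  reference n: %d   TS n: %d   seed: %d\n",
              x$ref_n, x$ts_n, x$seed))
  cat(sprintf("  log-noise SDs: %s\n",
              paste(sprintf("%s=%.4f", names(x$log_noise_sd), x$log_noise_sd),
                    collapse = " ")))
  cat(sprintf("  TS mixture: pi=%.3f delta=%.3f base_sd=%.4f center=%.3f\n",
              x$ts_mixture[["pi_affected"]], x$ts_mixture[["delta_shift"]],
              x$ts_mixture[["base_sd"]], x$ts_mixture[["center"]]))
  invisible(x)
}

#' Write / read a generator configuration as JSON
#'
#' The JSON sidecar echoes every field including the seed, so a cohort can be
#' regenerated exactly from its sidecar.
#'
#' @param config A `phalanx_config`.
#' @param path File path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a validated `phalanx_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "phalanx_config"))
  out <- unclass(config)
  # named vectors -> JSON objects, matrices -> column-named data frames, so
  # names survive the round trip
  out <- lapply(out, function(f) {
    if (is.matrix(f)) as.data.frame(f)
    else if (!is.null(names(f))) as.list(f)
    else f
  })
  out$format <- "phalanx-config/1"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "phalanx-config/1")) {
    abort_phalanx(sprintf("unsupported config format '%s' (expected phalanx-config/1)",
                          raw$format %||% "<missing>"),
                  class = "phalanx_version_error")
  }
  raw$format <- NULL
  for (f in c("ref_ratio_group_means", "mc_proportions", "mp_proportions")) {
    raw[[f]] <- as.matrix(as.data.frame(raw[[f]]))
  }
  for (f in c("log_noise_sd", "ts_ratio_means", "ts_ratio_sds", "ts_ratio_corr",
              "ts_mixture", "ts_severity_loading", "shox_sign_probs")) {
    raw[[f]] <- unlist(raw[[f]])
  }
  do.call(generator_config, raw)
}
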