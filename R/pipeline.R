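# End-to-end pipeline: simulate -> build-ref -> screen -> roc -> report.
# Stages communicate exclusively through files in `out_dir`, every artifact
# is deterministic given config + seed (no timestamps), and the config echo
# written alongside the outputs regenerates the run exactly.

artifact_path <- function(out_dir, name) file.path(out_dir, name)

#' Simulate both cohorts and write the cohort artifact files
#'
#' Writes `reference_lengths.csv`, `reference_metadata.csv`,
#' `reference_landmarks.csv`, the TS cohort (`ts_ratios.csv` for the
#' ratio-level backend, `ts_lengths.csv` for the length-level backend),
#' `ts_metadata.csv`, and a `config.json` echo of the full generator
#' configuration including the seed.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param backend TS backend, see [simulate_ts_cohort()].
#' @return Named character vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir,
                              backend = c("ratio_level", "length_level")) {
  backend <- match.arg(backend)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference_cohort(config)
  ts <- simulate_ts_cohort(config, backend = backend)
  paths <- c(
    reference_lengths = artifact_path(out_dir, "reference_lengths.csv"),
    reference_metadata = artifact_path(out_dir, "reference_metadata.csv"),
    reference_landmarks = artifact_path(out_dir, "reference_landmarks.csv"),
    ts_metadata = artifact_path(out_dir, "ts_metadata.csv"),
    config = artifact_path(out_dir, "config.json")
  )
  write_cohort_csv(ref$lengths, paths[["reference_lengths"]])
  write_cohort_csv(ref$subjects, paths[["reference_metadata"]])
  write_cohort_csv(emit_landmarks(ref$lengths,
                                  seed = stage_seed(config$seed, "landmarks")),
                   paths[["reference_landmarks"]])
  write_cohort_csv(ts$subjects, paths[["ts_metadata"]])
  if (backend == "ratio_level") {
    paths[["ts_ratios"]] <- artifact_path(out_dir, "ts_ratios.csv")
    write_cohort_csv(ts$ratios, paths[["ts_ratios"]])
  } else {
    paths[["ts_lengths"]] <- artifact_path(out_dir, "ts_lengths.csv")
    write_cohort_csv(ts$lengths, paths[["ts_lengths"]])
  }
  write_generator_config(config, paths[["config"]])
  invisible(paths)
}

#' Build and persist the trimmed reference table
#'
#' Reads the reference lengths and metadata from `out_dir`, computes ratios,
#' trims at `trim_limit` SDS (pooled z, union over ratios), and writes
#' `reference_ratios.csv` (retained subjects), `trim_report.json`,
#' `trim_excluded.csv` and the versioned `reference_table.json`.
#'
#' @param out_dir Directory holding the simulate-stage artifacts.
#' @param trim_limit Trimming limit in SDS (default 2.25).
#' @return The `phalanx_reference`, invisibly.
#' @export
pipeline_build_reference <- function(out_dir, trim_limit = 2.25) {
  lengths <- read_lengths(artifact_path(out_dir, "reference_lengths.csv"))
  metadata <- read_metadata(artifact_path(out_dir, "reference_metadata.csv"))
  ratios <- compute_ratios(lengths)
  trimmed <- trim_outliers(ratios, trim_limit = trim_limit)
  reference <- build_reference(trimmed$retained, metadata,
                               trim_limit = trim_limit)
  write_cohort_csv(trimmed$retained,
                   artifact_path(out_dir, "reference_ratios.csv"))
  write_cohort_csv(trimmed$report$excluded,
                   artifact_path(out_dir, "trim_excluded.csv"))
  report <- trimmed$report
  report$excluded <- NULL
  # keep names on the per-ratio vectors in the JSON
  report$n_excluded_per_ratio <- as.list(report$n_excluded_per_ratio)
  report$pooled_mean <- as.list(report$pooled_mean)
  report$pooled_sd <- as.list(report$pooled_sd)
  jsonlite::write_json(report, artifact_path(out_dir, "trim_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_reference(reference, artifact_path(out_dir, "reference_table.json"))
  invisible(reference)
}

read_ts_ratios <- function(out_dir) {
  ratio_path <- artifact_path(out_dir, "ts_ratios.csv")
  if (file.exists(ratio_path)) {
    read_ratios(ratio_path)
  } else {
    compute_ratios(read_lengths(artifact_path(out_dir, "ts_lengths.csv")))
  }
}

filter_min_age <- function(ratios, metadata, min_bone_age) {
  if (is.null(min_bone_age)) return(ratios)
  keep <- metadata$subject_id[metadata$bone_age >= min_bone_age]
  ratios[ratios$subject_id %in% keep, ]
}

#' Screen the TS cohort against the persisted reference table
#'
#' Reads `reference_table.json` (refusing any schema version other than
#' `phalanx-ref/1`), screens the TS cohort, and writes `screening.csv` plus
#' `prevalence.json` (TS flag and SHOX-sign prevalences, each compared to
#' the self-screened retained reference cohort by chi-square/Fisher).
#'
#' @param out_dir Directory holding the earlier artifacts.
#' @param mc_sds,bda3_threshold Flag thresholds (defaults -2 SDS and 0.5).
#' @param min_bone_age Optional lower bone-age bound applied to both cohorts
#'   before screening.
#' @return The TS screening tibble, invisibly.
#' @export
pipeline_screen <- function(out_dir, mc_sds = -2, bda3_threshold = 0.5,
                            min_bone_age = NULL) {
  reference <- read_reference(artifact_path(out_dir, "reference_table.json"))
  ts_meta <- read_metadata(artifact_path(out_dir, "ts_metadata.csv"))
  ts_ratios <- filter_min_age(read_ts_ratios(out_dir), ts_meta, min_bone_age)
  ref_meta <- read_metadata(artifact_path(out_dir, "reference_metadata.csv"))
  ref_ratios <- filter_min_age(
    read_ratios(artifact_path(out_dir, "reference_ratios.csv")),
    ref_meta, min_bone_age)

  ts_screen <- screen_cohort(ts_ratios, ts_meta, reference,
                             mc_sds = mc_sds,
                             bda3_threshold = bda3_threshold)
  ref_screen <- screen_cohort(ref_ratios, ref_meta, reference,
                              mc_sds = mc_sds,
                              bda3_threshold = bda3_threshold)
  prevalence <- cohort_prevalence(
    ts_screen,
    shox_annotations = ts_meta[ts_meta$subject_id %in% ts_screen$subject_id, ],
    compare_to = list(results = ref_screen)
  )
  write_cohort_csv(ts_screen, artifact_path(out_dir, "screening.csv"))
  jsonlite::write_json(prevalence, artifact_path(out_dir, "prevalence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(ts_screen)
}

#' ROC analysis of the three ratios, persisted as JSON
#'
#' Runs [roc_analysis()] for each ratio (TS vs retained reference), with the
#' fixed operating point reported for the 4:3 MC ratio, and writes
#' `roc.json`.
#'
#' @inheritParams pipeline_screen
#' @param cutoff Fixed 4:3 MC cutoff to report an operating point at
#'   (default 0.876).
#' @return Named list of `phalanx_roc` objects, invisibly.
#' @export
pipeline_roc <- function(out_dir, cutoff = 0.876, min_bone_age = NULL) {
  ts_meta <- read_metadata(artifact_path(out_dir, "ts_metadata.csv"))
  ref_meta <- read_metadata(artifact_path(out_dir, "reference_metadata.csv"))
  ts_ratios <- filter_min_age(read_ts_ratios(out_dir), ts_meta, min_bone_age)
  ref_ratios <- filter_min_age(
    read_ratios(artifact_path(out_dir, "reference_ratios.csv")),
    ref_meta, min_bone_age)
  results <- lapply(RATIO_COLS, function(k) {
    roc_analysis(ref_ratios[[k]], ts_ratios[[k]],
                 cutoff = if (k == "r43mc") cutoff else NULL)
  })
  names(results) <- RATIO_COLS
  payload <- lapply(results, function(r) {
    out <- list(auc = r$auc, auc_ci_low = r$auc_ci_low,
                auc_ci_high = r$auc_ci_high, n_ref = r$n_ref, n_ts = r$n_ts,
                orientation = r$orientation, youden = as.list(r$youden))
    if (!is.null(r$fixed_cutoff)) out$fixed_cutoff <- as.list(r$fixed_cutoff)
    out
  })
  jsonlite::write_json(payload, artifact_path(out_dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Assemble the markdown run report from the artifacts alone
#'
#' Every table cell in `report.md` is read back from the persisted artifacts
#' — nothing is recomputed — so regenerating the report from the same
#' artifacts reproduces it byte for byte.
#'
#' @param out_dir Directory holding the pipeline artifacts.
#' @return The report path, invisibly.
#' @export
pipeline_report <- function(out_dir) {
  reference <- read_reference(artifact_path(out_dir, "reference_table.json"))
  trim <- jsonlite::read_json(artifact_path(out_dir, "trim_report.json"),
                              simplifyVector = TRUE)
  prevalence <- jsonlite::read_json(artifact_path(out_dir, "prevalence.json"),
                                    simplifyVector = TRUE)
  roc <- jsonlite::read_json(artifact_path(out_dir, "roc.json"),
                             simplifyVector = TRUE)
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "f")
  lines <- c(
    "# Phalangeal ratio pipeline report", "",
    "## Trimming", "",
    sprintf("- subjects in: %d; excluded (|z| > %s on any ratio): %d; retained: %d",
            trim$n_input, fmt(trim$trim_limit, 2), trim$n_excluded_total,
            trim$n_retained), "",
    "## Pooled reference ratios", "",
    "| ratio | n | mean | sd |", "|---|---|---|---|",
    sprintf("| %s | %d | %s | %s |", reference$pooled$ratio,
            reference$pooled$n, fmt(reference$pooled$mean),
            fmt(reference$pooled$sd)), "",
    "## TS flag prevalence", "",
    "| measure | count | n | proportion | test | p |", "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %s | %s | %s |", prevalence$measure,
            prevalence$count, prevalence$n, fmt(prevalence$proportion),
            prevalence$method, fmt(prevalence$p_value)), "",
    "## ROC (lower ratio indicates TS)", "",
    "| ratio | AUC | 95% CI | Youden cutoff | J | sens | spec |",
    "|---|---|---|---|---|---|---|",
    vapply(names(roc), function(k) {
      r <- roc[[k]]
      sprintf("| %s | %s | %s-%s | %s | %s | %s | %s |", k, fmt(r$auc, 3),
              fmt(r$auc_ci_low, 3), fmt(r$auc_ci_high, 3),
              fmt(r$youden$cutoff), fmt(r$youden$j, 3),
              fmt(r$youden$sensitivity, 3), fmt(r$youden$specificity, 3))
    }, character(1)), ""
  )
  path <- artifact_path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate -> build-ref -> (optionally refit the TS 4:3 MC mixture against
#' the freshly built table, regenerating the TS cohort and the config echo)
#' -> screen -> roc -> report. All randomness flows from `config$seed`;
#' identical config and seed give byte-identical artifacts.
#'
#' @param out_dir Output directory.
#' @param config A [generator_config()].
#' @param backend TS backend (see [simulate_ts_cohort()]).
#' @param trim_limit Trimming limit in SDS.
#' @param cutoff Fixed 4:3 MC cutoff for the ROC operating point.
#' @param min_bone_age Optional lower bone-age bound for screening/ROC.
#' @param refit_mixture Refit `ts_mixture` against the built table (default
#'   `TRUE` for the ratio-level backend).
#' @param mixture_targets Targets for the refit:
#'   `c(mean, sd, flag_prev)` of the TS 4:3 MC ratio.
#' @return Invisible list with the `reference` table, TS `screening` tibble
#'   and `roc` results.
#' @export
run_pipeline <- function(out_dir, config = generator_config(),
                         backend = c("ratio_level", "length_level"),
                         trim_limit = 2.25, cutoff = 0.876,
                         min_bone_age = NULL,
                         refit_mixture = (backend == "ratio_level"),
                         mixture_targets = c(mean = 0.860, sd = 0.050,
                                             flag_prev = 0.272)) {
  backend <- match.arg(backend)
  force(refit_mixture)
  pipeline_simulate(config, out_dir, backend = backend)
  reference <- pipeline_build_reference(out_dir, trim_limit = trim_limit)
  if (refit_mixture && backend == "ratio_level") {
    config$ts_mixture <- fit_ts_mixture(
      reference, mixture_targets[["mean"]], mixture_targets[["sd"]],
      mixture_targets[["flag_prev"]])
    ts <- simulate_ts_cohort(config, backend = backend)
    write_cohort_csv(ts$ratios, artifact_path(out_dir, "ts_ratios.csv"))
    write_cohort_csv(ts$subjects, artifact_path(out_dir, "ts_metadata.csv"))
    write_generator_config(config, artifact_path(out_dir, "config.json"))
  }
  screening <- pipeline_screen(out_dir, min_bone_age = min_bone_age)
  roc <- pipeline_roc(out_dir, cutoff = cutoff, min_bone_age = min_bone_age)
  pipeline_report(out_dir)
  invisible(list(reference = reference, screening = screening, roc = roc))
}
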