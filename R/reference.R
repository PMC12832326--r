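#' Assign bone-age groups
#'
#' Six groups aligned with pubertal developmental stages:
#' Group 1 0-5.9 y (young childhood), 2 6.0-7.9 y (prepubertal),
#' 3 8.0-10.9 y (early pubertal), 4 11.0-12.9 y (midpubertal),
#' 5 13.0-14.9 y (late pubertal), 6 15.0-18.0 y (postpubertal).
#' Bins are half-open on the right except the top bin, which is closed at 18.
#'
#' @param bone_age Numeric vector of bone ages in years, each in \[0, 18\].
#' @return Integer vector of group indices 1-6.
#' @examples
#' assign_age_group(c(5.9, 6.0, 18.0))
#' @export
assign_age_group <- function(bone_age) {
  if (any(!is.finite(bone_age) | bone_age < 0 | bone_age > 18)) {
    abort_phalanx("bone_age must lie in [0, 18] years",
                  class = "phalanx_age_error")
  }
  as.integer(pmin(findInterval(bone_age, AGE_BREAKS[-7L]), 6L))
}

#' Trim ratio outliers by pooled z-score
#'
#' Single pass: pooled (all-age) mean and SD are computed per ratio on the
#' input sample; a subject is excluded when `|z| > trim_limit` on ANY of the
#' three ratios (union rule, strict inequality, so a subject exactly at the
#' limit is retained). Exclusion decisions depend only on the input-sample
#' moments — the pass is not iterated. A ratio with zero SD contributes no
#' exclusions (degenerate-distribution guard, with a warning).
#'
#' @param ratios Tibble `subject_id, r43mc, r53mc, r53mp` with at least 10
#'   subjects.
#' @param trim_limit Positive z-score limit in SDS (default 2.25).
#' @return List of class `phalanx_trim` with `retained` (tibble) and
#'   `report`: `n_input`, `n_excluded_per_ratio`, `n_excluded_total` (union),
#'   `n_retained`, and `excluded` (tibble `subject_id, reason`).
#' @export
trim_outliers <- function(ratios, trim_limit = 2.25) {
  check_columns(ratios, c("subject_id", RATIO_COLS), "ratios table")
  if (nrow(ratios) < 10L) {
    abort_phalanx("trimming requires at least 10 subjects",
                  class = "phalanx_trim_error")
  }
  if (trim_limit <= 0) {
    abort_phalanx("trim_limit must be > 0", class = "phalanx_trim_error")
  }
  vals <- as.matrix(ratios[RATIO_COLS])
  means <- colMeans(vals)
  sds <- apply(vals, 2L, stats::sd)
  out_mat <- matrix(FALSE, nrow(vals), 3L, dimnames = list(NULL, RATIO_COLS))
  for (k in seq_along(RATIO_COLS)) {
    if (sds[k] == 0) {
      rlang::warn(sprintf("ratio %s has zero SD; no exclusions applied to it",
                          RATIO_COLS[k]))
      next
    }
    out_mat[, k] <- abs((vals[, k] - means[k]) / sds[k]) > trim_limit
  }
  excluded_any <- rowSums(out_mat) > 0
  reason <- apply(out_mat, 1L, function(r) paste(RATIO_COLS[r], collapse = "+"))
  report <- list(
    n_input = nrow(ratios),
    n_excluded_per_ratio = colSums(out_mat),
    n_excluded_total = sum(excluded_any),
    n_retained = sum(!excluded_any),
    trim_limit = trim_limit,
    pooled_mean = means,
    pooled_sd = sds,
    excluded = tibble::tibble(subject_id = ratios$subject_id[excluded_any],
                              reason = paste0("|z|>", trim_limit, " on ",
                                              reason[excluded_any]))
  )
  structure(list(retained = ratios[!excluded_any, ], report = report),
            class = "phalanx_trim")
}

#' @export
print.phalanx_trim <- function(x, ...) {
  r <- x$report
  cat(sprintf("<phalanx_trim: %d in, %d excluded (|z| > %.2f), %d retained>\n",
              r$n_input, r$n_excluded_total, r$trim_limit, r$n_retained))
  invisible(x)
}

#' Build the age-stratified normative reference table
#'
#' Per bone-age group and pooled: n, mean and SD (n-1 denominator) of each of
#' the three ratios, computed on the trimmed sample. A group with n < 2 keeps
#' its row with `sd = NA`; screening against such a group refuses explicitly.
#'
#' @param retained Tibble of (typically trimmed) ratios,
#'   `subject_id, r43mc, r53mc, r53mp`.
#' @param metadata Tibble with `subject_id` and `bone_age` for every retained
#'   subject.
#' @param trim_limit The z-score limit the sample was trimmed at, recorded in
#'   the table (default 2.25).
#' @return Object of class `phalanx_reference`: tibbles `groups`
#'   (`age_group, ratio, n, mean, sd`) and `pooled` (`ratio, n, mean, sd`),
#'   plus `trim_limit` and a `provenance` record (input hash, sizes, package
#'   version, schema `phalanx-ref/1`).
#' @export
build_reference <- function(retained, metadata, trim_limit = 2.25) {
  check_columns(retained, c("subject_id", RATIO_COLS), "ratios table")
  check_columns(metadata, c("subject_id", "bone_age"), "metadata table")
  missing_meta <- setdiff(retained$subject_id, metadata$subject_id)
  if (length(missing_meta) > 0L) {
    abort_phalanx(
      sprintf("no metadata row for %d subject(s), e.g. %s",
              length(missing_meta), missing_meta[1]),
      class = "phalanx_reference_error"
    )
  }
  joined <- dplyr::inner_join(retained,
                              metadata[c("subject_id", "bone_age")],
                              by = "subject_id")
  joined$age_group <- assign_age_group(joined$bone_age)
  long <- tidyr::pivot_longer(joined, dplyr::all_of(RATIO_COLS),
                              names_to = "ratio", values_to = "value")
  groups <- long |>
    dplyr::group_by(.data$age_group, .data$ratio) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = ifelse(dplyr::n() >= 2L, stats::sd(.data$value),
                                 NA_real_),
                     .groups = "drop") |>
    dplyr::arrange(.data$age_group, .data$ratio)
  # materialize empty groups so lookups fail loudly rather than silently
  grid <- tidyr::expand_grid(age_group = 1:6, ratio = RATIO_COLS)
  groups <- dplyr::left_join(grid, groups, by = c("age_group", "ratio")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  pooled <- long |>
    dplyr::group_by(.data$ratio) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = ifelse(dplyr::n() >= 2L, stats::sd(.data$value),
                                 NA_real_),
                     .groups = "drop")
  structure(
    list(groups = groups, pooled = pooled, trim_limit = trim_limit,
         provenance = list(format = "phalanx-ref/1",
                           input_hash = rlang::hash(joined),
                           n_subjects = nrow(joined),
                           package_version = as.character(
                             utils::packageVersion("phalanx")))),
    class = "phalanx_reference"
  )
}

#' @export
print.phalanx_reference <- function(x, ...) {
  cat(sprintf("<phalanx_reference: n = %d, trim limit %.2f SDS>\n",
              x$provenance$n_subjects, x$trim_limit))
  cat("pooled:\n")
  print(as.data.frame(x$pooled), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn build_reference `tidy()` returns the per-group rows.
#' @param x A `phalanx_reference`.
#' @param ... Unused.
#' @export
tidy.phalanx_reference <- function(x, ...) x$groups

#' @describeIn build_reference `glance()` returns the pooled rows.
#' @export
glance.phalanx_reference <- function(x, ...) x$pooled

#' Serialize / deserialize a reference table as versioned JSON
#'
#' Schema `phalanx-ref/1`; numeric fields are written at full precision so
#' the round trip is lossless to better than 1e-12.
#'
#' @param reference A `phalanx_reference`.
#' @param path JSON file path.
#' @return `write_reference()` returns `path` invisibly; `read_reference()`
#'   the reconstructed `phalanx_reference`.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "phalanx_reference"))
  payload <- list(
    format = "phalanx-ref/1",
    trim_limit = reference$trim_limit,
    provenance = reference$provenance,
    groups = reference$groups,
    pooled = reference$pooled
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "phalanx-ref/1")) {
    abort_phalanx(
      sprintf("unsupported reference format '%s' (expected phalanx-ref/1)",
              raw$format %||% "<missing>"),
      class = "phalanx_version_error"
    )
  }
  denull <- function(col) {
    if (is.list(col))

      vapply(col, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    else col
  }
  groups <- tibble::as_tibble(lapply(raw$groups, denull))
  pooled <- tibble::as_tibble(lapply(raw$pooled, denull))
  groups$sd <- as.numeric(groups$sd)
  pooled$sd <- as.numeric(pooled$sd)
  groups$age_group <- as.integer(groups$age_group)
  groups$n <- as.integer(groups$n)
  pooled$n <- as.integer(pooled$n)
  structure(list(groups = groups, pooled = pooled,
                 trim_limit = raw$trim_limit, provenance = raw$provenance),
            class = "phalanx_reference")
}

#' Skewness and excess kurtosis diagnostics
#'
#' Sample skewness and EXCESS kurtosis (normal -> 0) with the bias-adjusted
#' small-sample convention used by mainstream statistics suites
#' (`e1071` type 2). The excess convention is the one under which near-normal
#' data can print small negative kurtosis.
#'
#' @param values Numeric vector, n >= 4, non-degenerate.
#' @return One-row tibble `n, skewness, excess_kurtosis`.
#' @export
distribution_diagnostics <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) {
    abort_phalanx("distribution diagnostics require n >= 4",
                  class = "phalanx_diagnostics_error")
  }
  if (stats::sd(values) == 0) {
    abort_phalanx("zero variance: skewness/kurtosis undefined",
                  class = "phalanx_diagnostics_error")
  }
  tibble::tibble(
    n = n,
    skewness = e1071::skewness(values, type = 2),
    excess_kurtosis = e1071::kurtosis(values, type = 2)
  )
}

#' Diagnostics for all three ratios of a cohort
#'
#' @param ratios Tibble with the three ratio columns.
#' @return Tibble `ratio, n, skewness, excess_kurtosis`.
#' @export
ratio_diagnostics <- function(ratios) {
  check_columns(ratios, RATIO_COLS, "ratios table")
  purrr::map_dfr(RATIO_COLS, function(k) {
    dplyr::bind_cols(tibble::tibble(ratio = k),
                     distribution_diagnostics(ratios[[k]]))
  })
}
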