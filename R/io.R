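# CSV readers/writers for the cohort artifact files. Dialect: comma-separated,
# '.' decimal, UTF-8, header required. Malformed rows are collected into a
# "rejects" attribute, never silently dropped; structural problems (missing
# columns, duplicate keys, unknown enum values) are hard errors.

read_cohort_csv <- function(path, required, what) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(data, required, what)
  tibble::as_tibble(data)
}

collect_rejects <- function(data, bad, reason) {
  tibble::tibble(subject_id = as.character(data$subject_id[bad]),
                 reason = reason)
}

#' Read landmark annotations from CSV
#'
#' Expects columns `subject_id, bone, base_x, base_y, head_x, head_y` with
#' bones among MC3, MC4, MC5, MP3, MP5. Duplicate (subject_id, bone) pairs
#' and unknown bone values are hard errors; rows with non-finite coordinates
#' are moved to the `"rejects"` attribute.
#'
#' @param path CSV file path.
#' @return Tibble of validated annotations.
#' @export
read_annotations <- function(path) {
  data <- read_cohort_csv(
    path, c("subject_id", "bone", "base_x", "base_y", "head_x", "head_y"),
    "annotations file")
  bad_bone <- setdiff(unique(data$bone), BONES)
  if (length(bad_bone) > 0L) {
    abort_phalanx(
      sprintf("unknown bone value(s) %s; allowed: %s",
              paste(bad_bone, collapse = ", "), paste(BONES, collapse = ", ")),
      class = "phalanx_parse_error"
    )
  }
  dup <- duplicated(data[c("subject_id", "bone")])
  if (any(dup)) {
    abort_phalanx(
      sprintf("duplicate (subject_id, bone) pair(s): %s",
              paste(data$subject_id[dup], data$bone[dup], sep = "/",
                    collapse = ", ")),
      class = "phalanx_parse_error"
    )
  }
  coords <- as.matrix(data[c("base_x", "base_y", "head_x", "head_y")])
  bad <- apply(coords, 1L, function(r) any(!is.finite(r)))
  out <- data[!bad, ]
  attr(out, "rejects") <- collect_rejects(data, bad, "non_finite_coordinates")
  out
}

#' Read a bone-lengths table from CSV
#'
#' Expects columns `subject_id, mc3, mc4, mc5, mp3, mp5`. Duplicate subject
#' ids are a hard error; rows with non-numeric or non-finite lengths go to
#' the `"rejects"` attribute (non-positive lengths are left for
#' [compute_ratios()] to reject with a subject-level reason).
#'
#' @param path CSV file path.
#' @return Tibble of validated lengths.
#' @export
read_lengths <- function(path) {
  data <- read_cohort_csv(path, c("subject_id", LENGTH_COLS), "lengths file")
  dup <- duplicated(data$subject_id)
  if (any(dup)) {
    abort_phalanx(sprintf("duplicate subject_id(s): %s",
                          paste(unique(data$subject_id[dup]), collapse = ", ")),
                  class = "phalanx_parse_error")
  }
  vals <- as.matrix(data[LENGTH_COLS])
  bad <- apply(vals, 1L, function(r) any(is.na(r)))
  out <- data[!bad, ]
  attr(out, "rejects") <- collect_rejects(data, bad, "non_numeric_length")
  out
}

#' Read subject metadata from CSV
#'
#' Expects the metadata dialect written by [pipeline_simulate()]:
#' `subject_id, cohort, bone_age, age_group, karyotype, gh_treated,
#' height_percentile, shox_triangularization, shox_lucency,
#' shox_pyramidalization`. Rows whose `age_group` is inconsistent with
#' `bone_age` under the group bounds are rejected.
#'
#' @param path CSV file path.
#' @return Tibble of validated subject records.
#' @export
read_metadata <- function(path) {
  data <- read_cohort_csv(
    path, c("subject_id", "cohort", "bone_age", "age_group"), "metadata file")
  dup <- duplicated(data$subject_id)
  if (any(dup)) {
    abort_phalanx(sprintf("duplicate subject_id(s): %s",
                          paste(unique(data$subject_id[dup]), collapse = ", ")),
                  class = "phalanx_parse_error")
  }
  bad_age <- !is.finite(data$bone_age) | data$bone_age < 0 | data$bone_age > 18
  consistent <- rep(FALSE, nrow(data))
  consistent[!bad_age] <-
    assign_age_group(data$bone_age[!bad_age]) == data$age_group[!bad_age]
  bad <- bad_age | !consistent
  out <- data[!bad, ]
  attr(out, "rejects") <- collect_rejects(
    data, bad, ifelse(bad_age[bad], "bone_age_out_of_range",
                      "age_group_inconsistent"))
  out
}

#' Read a ratio table from CSV
#'
#' Expects columns `subject_id, r43mc, r53mc, r53mp`.
#'
#' @param path CSV file path.
#' @return Tibble of ratios; malformed rows in `attr(, "rejects")`.
#' @export
read_ratios <- function(path) {
  data <- read_cohort_csv(path, c("subject_id", RATIO_COLS), "ratios file")
  vals <- as.matrix(data[RATIO_COLS])
  bad <- apply(vals, 1L, function(r) any(!is.finite(r) | r <= 0 | r >= 2))
  out <- data[!bad, ]
  attr(out, "rejects") <- collect_rejects(data, bad, "ratio_missing_or_out_of_range")
  out
}

#' Write cohort artifact CSV files
#'
#' Thin wrappers over [readr::write_csv()] fixing the documented dialect.
#'
#' @param data Tibble to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
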