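#' Bone length from landmark annotations
#'
#' The measurement convention is the Euclidean distance from the midpoint of
#' the base to the midpoint of the distal end of each bone, in (sub-)pixel
#' units. Only coordinate differences enter, so lengths are invariant under
#' translation and rotation of the image.
#'
#' @param annotations Tibble with columns
#'   `subject_id, bone, base_x, base_y, head_x, head_y`.
#' @return The input with a `length` column appended (pixels).
#' @examples
#' bone_length(tibble::tibble(subject_id = "S1", bone = "MC3",
#'                            base_x = 0, base_y = 0, head_x = 3, head_y = 4))
#' @export
bone_length <- function(annotations) {
  check_columns(annotations,
                c("subject_id", "bone", "base_x", "base_y", "head_x", "head_y"),
                "annotations table")
  coords <- annotations[c("base_x", "base_y", "head_x", "head_y")]
  if (any(!vapply(coords, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(coords)))) {
    abort_phalanx("landmark coordinates must be finite numerics",
                  class = "phalanx_measure_error")
  }
  len <- sqrt((annotations$head_x - annotations$base_x)^2 +
                (annotations$head_y - annotations$base_y)^2)
  zero <- len == 0
  if (any(zero)) {
    bad <- annotations[zero, c("subject_id", "bone")]
    abort_phalanx(
      sprintf("coincident landmarks (zero length) for: %s",
              paste(bad$subject_id, bad$bone, sep = "/", collapse = ", ")),
      class = "phalanx_measure_error"
    )
  }
  dplyr::mutate(annotations, length = len)
}

#' Per-subject wide table of bone lengths from annotations
#'
#' @param annotations As in [bone_length()]; one row per (subject, bone),
#'   bones among MC3, MC4, MC5, MP3, MP5.
#' @return Tibble `subject_id, mc3, mc4, mc5, mp3, mp5` (pixels); missing
#'   bones appear as `NA` and are rejected later by [compute_ratios()].
#' @export
measure_lengths <- function(annotations) {
  measured <- bone_length(annotations)
  bad_bone <- setdiff(unique(measured$bone), BONES)
  if (length(bad_bone) > 0L) {
    abort_phalanx(
      sprintf("unknown bone value(s) %s; allowed: %s",
              paste(bad_bone, collapse = ", "), paste(BONES, collapse = ", ")),
      class = "phalanx_parse_error"
    )
  }
  dup <- duplicated(measured[c("subject_id", "bone")])
  if (any(dup)) {
    abort_phalanx(
      sprintf("duplicate (subject_id, bone) pair(s): %s",
              paste(measured$subject_id[dup], measured$bone[dup],
                    sep = "/", collapse = ", ")),
      class = "phalanx_parse_error"
    )
  }
  wide <- tidyr::pivot_wider(
    dplyr::mutate(measured, bone = tolower(.data$bone)),
    id_cols = "subject_id", names_from = "bone", values_from = "length"
  )
  for (col in setdiff(LENGTH_COLS, names(wide))) wide[[col]] <- NA_real_
  wide[c("subject_id", LENGTH_COLS)]
}

#' Compute the three phalangeal length ratios
#'
#' Per subject: 4:3 MC = MC4/MC3, 5:3 MC = MC5/MC3, 5:3 MP = MP5/MP3. Because
#' relative ratios rather than absolute lengths are analysed (magnification
#' varies per image), a subject needs all five bones: subjects with missing or
#' non-positive lengths, or with any ratio outside (0, 2), are dropped as a
#' whole and collected — with reason codes — in the `"rejected"` attribute,
#' never silently.
#'
#' @param lengths Tibble `subject_id, mc3, mc4, mc5, mp3, mp5`.
#' @return Tibble `subject_id, r43mc, r53mc, r53mp`; rejected subjects in
#'   `attr(, "rejected")` as a tibble `subject_id, reason`.
#' @examples
#' compute_ratios(tibble::tibble(subject_id = "S1", mc3 = 60, mc4 = 53.34,
#'                               mc5 = 49.32, mp3 = 30, mp5 = 18.6))
#' @export
compute_ratios <- function(lengths) {
  check_columns(lengths, c("subject_id", LENGTH_COLS), "lengths table")
  mat <- as.matrix(lengths[LENGTH_COLS])
  missing_or_nonpos <- apply(mat, 1L, function(r) any(!is.finite(r) | r <= 0))
  ratios <- tibble::tibble(
    subject_id = lengths$subject_id,
    r43mc = unname(mat[, "mc4"] / mat[, "mc3"]),
    r53mc = unname(mat[, "mc5"] / mat[, "mc3"]),
    r53mp = unname(mat[, "mp5"] / mat[, "mp3"])
  )
  out_of_range <- !missing_or_nonpos &
    apply(as.matrix(ratios[RATIO_COLS]), 1L,
          function(r) any(r <= 0 | r >= 2))
  reject <- missing_or_nonpos | out_of_range
  rejected <- tibble::tibble(
    subject_id = lengths$subject_id[reject],
    reason = ifelse(missing_or_nonpos[reject],
                    "missing_or_nonpositive_length", "ratio_out_of_range")
  )
  out <- ratios[!reject, ]
  attr(out, "rejected") <- rejected
  out
}
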