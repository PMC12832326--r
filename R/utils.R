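# Shared constants and small internal helpers.

# Bone-age group bounds in years: [0,6) [6,8) [8,11) [11,13) [13,15) [15,18].
AGE_BREAKS <- c(0, 6, 8, 11, 13, 15, 18)

BONES <- c("MC3", "MC4", "MC5", "MP3", "MP5")
LENGTH_COLS <- c("mc3", "mc4", "mc5", "mp3", "mp5")
RATIO_COLS <- c("r43mc", "r53mc", "r53mp")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_phalanx <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "phalanx_error"), ...)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort_phalanx(
      sprintf("%s is missing mandatory column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "phalanx_parse_error"
    )
  }
  invisible(data)
}

# Stage seeds are small offsets from the user seed so that independent draw
# families (e.g. magnification) live in separate substreams; offsets stay
# well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(main = 0L, magnification = 1L, ts = 2L, ts_magnification = 3L,
               landmarks = 4L)
  as.integer(seed) + offsets[[stage]]
}
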