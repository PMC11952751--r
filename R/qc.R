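#' Recording-quality filter on series resistance
#'
#' Excludes cells whose pipette series resistance exceeds `rs_max` MOhm —
#' the quality gate applied before analysing fast AP-waveform parameters
#' (half-width, up-stroke, amplitude, rheobase), where access resistance
#' distorts the measurement most. Works on a list of [cell_record()]s or on
#' a feature tibble with a `series_resistance` column; cells with missing
#' series resistance are kept by default.
#'
#' @param x List of records, or a data frame.
#' @param rs_max Maximum admissible series resistance (MOhm, default 30).
#' @param keep_missing Keep entries with unknown series resistance.
#' @return Filtered object of the same shape, with attribute `n_excluded`.
#' @export
qc_filter <- function(x, rs_max = 30, keep_missing = TRUE) {
  if (is.data.frame(x)) {
    rs <- x$series_resistance
    keep <- if (keep_missing) is.na(rs) | rs <= rs_max
            else !is.na(rs) & rs <= rs_max
    out <- x[keep, , drop = FALSE]
  } else {
    rs <- vapply(x, function(r) r$series_resistance, numeric(1))
    keep <- if (keep_missing) is.na(rs) | rs <= rs_max
            else !is.na(rs) & rs <= rs_max
    out <- x[keep]
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}
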