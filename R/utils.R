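#' Round half away from zero
#'
#' Commercial rounding as used for the printed rates and shares: exact
#' halves round away from zero (base `round()` rounds half to even, which
#' would print 4,143/99,457 as 4.2% either way but differs on exact .x5
#' values).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# fast ISO-8601 date parser; returns NA for malformed input, never warns
.parse_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

.fmt_date <- function(d) {
  out <- format(d, "%Y-%m-%d")
  out[is.na(out)] <- ""
  out
}

# split a semicolon-delimited multi-value cell into a character vector
.split_multi <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

.join_multi <- function(lst) {
  vapply(lst, paste, character(1), collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
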