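#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for display tables, where base R's
#' [round()] rounds half to even. Only affects values exactly on a half.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Stop with the offending field named, for config validation.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

check_positive <- function(x, field) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
             field, "must be a single positive finite number")
}

check_nonneg <- function(x, field) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0,
             field, "must be a single non-negative finite number")
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
# NULL seed means "use whatever stream is active".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
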