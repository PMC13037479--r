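#' Round half away from zero at a fixed number of decimals
#'
#' Base R `round()` rounds half to even; printed percentages in sorting
#' summary tables use conventional half-up rounding (78.947 -> 78.95), so all
#' reported percentages go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(78.94736, 2)  # 78.95
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards against values like 2.4499999... that are exactly
  # .5 in decimal but fall just below it in binary
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# log(sum(exp(x))) without overflow; -Inf entries allowed
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  if (any(is.na(x)) || any(x < 0 | x > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_pos <- function(x, field) {
  if (any(is.na(x)) || any(x <= 0)) stop_field(field, "must be positive")
  invisible(x)
}

# one structured log line per pipeline stage so filter attrition is auditable
log_stage <- function(stage, n_in, n_out, quiet = getOption("viroturn.quiet", TRUE)) {
  if (!quiet) {
    message(sprintf("[viroturn] %-18s in=%d out=%d", stage, n_in, n_out))
  }
  invisible(NULL)
}
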