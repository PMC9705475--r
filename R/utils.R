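#' Round half away from zero
#'
#' Rounds with ties going away from zero, the convention used for all
#' reported screening rates and volume-reduction percentages in this
#' package (so 62.5 rounds to 63, unlike [base::round()]'s banker's
#' rounding).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(62.5)       # 63
#' round_half_up(6.489, 1)   # 6.5
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a call-free, sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

check_prob_vector <- function(x, name, len = 10L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < 0)) {
    abort("%s must be a non-negative numeric vector of length %d", name, len)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort("%s must sum to 1 (got %.12f)", name, sum(x))
  }
  invisible(x)
}
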