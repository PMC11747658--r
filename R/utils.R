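#' Round half away from zero at a fixed number of decimals
#'
#' Published pharmacovigilance tables round percentages half-up (2.45 -> 2.5),
#' unlike R's banker's rounding. Used wherever the package reproduces a
#' printed percentage.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(11.747, 0.25), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Recover a ratio point estimate from its log-symmetric confidence bounds
#'
#' Woolf-type intervals are symmetric on the log scale, so the point estimate
#' is the geometric mean of the bounds: `sqrt(low * high)`. Useful to check
#' published ROR tables for internal consistency.
#'
#' @param ci_low,ci_high interval bounds (vectors).
#' @return numeric vector of point estimates.
#' @export
#' @examples
#' ror_from_ci(7.29, 9.42)
ror_from_ci <- function(ci_low, ci_high) {
  stopifnot(all(ci_low > 0, na.rm = TRUE), all(ci_high > 0, na.rm = TRUE))
  sqrt(ci_low * ci_high)
}

# log(exp(la) + exp(lb)) without overflow, elementwise
logsumexp2 <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log(exp(la - m) + exp(lb - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# "24Q1"-style quarter label from a YYYYMMDD date string
quarter_label <- function(fda_dt) {
  y <- substr(fda_dt, 3, 4)
  m <- as.integer(substr(fda_dt, 5, 6))
  paste0(y, "Q", (m - 1L) %/% 3L + 1L)
}
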