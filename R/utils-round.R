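#' Round half up at a fixed number of decimals
#'
#' Decimal (not binary-float) rounding: values exactly halfway between two
#' representable decimals round away from zero, so `round_half_up(0.625)` is
#' 0.63 where base [round()] (round-half-even) gives 0.62. All published
#' tables in the PMC index literature use this convention, and the scoring
#' pipeline applies it at both the main-indicator and the index stage.
#'
#' A small guard (1e-9) absorbs binary representation error in ratios such as
#' 5/12 before the half-up decision is taken.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(0.625, 0.875, 5 / 12))
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: format scores with fixed 2-decimal printing for CSV writers
format_score <- function(x) formatC(x, format = "f", digits = 2)
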