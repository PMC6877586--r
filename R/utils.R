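#' Round half away from zero
#'
#' Deterministic decimal rounding in which a value exactly halfway between
#' two neighbours moves away from zero (so 15.45 -> 15.5 at one decimal),
#' matching the convention used for all printed percentages in this package.
#' Base [round()] uses IEC 60559 banker's rounding, which would make reported
#' percentages depend on the parity of the neighbouring digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(15.448, 1)  # 15.4
#' round_half_up(1.545, 2)   # 1.55
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop unless all conditions hold; `...` are named logical scalars
#' @noRd
stopifnot_named <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(all(conds[[nm]]))) stop(nm, call. = FALSE)
  }
  invisible(TRUE)
}

# upper-case, unique, NA-free symbol set
#' @noRd
normalize_symbols <- function(x) {
  x <- toupper(as.character(x))
  unique(x[!is.na(x) & nzchar(x)])
}
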