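# Internal helpers: error signalling, presentation rounding, unit conversion.

abort_domain <- function(msg, class = "sbmetrics_domain_error") {
  rlang::abort(msg, class = c(class, "sbmetrics_error"))
}

abort_inconsistency <- function(msg) {
  abort_domain(msg, class = "sbmetrics_inconsistency_error")
}

check_numeric <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort_domain(sprintf("`%s` must be numeric, not %s.", name, class(x)[1]))
  }
  if (!allow_na && anyNA(x)) {
    abort_domain(sprintf("`%s` contains missing values.", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_numeric(x, name)
  if (any(x < 0)) {
    abort_domain(sprintf("`%s` must be non-negative (offending index %d).",
                         name, which(x < 0)[1]))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Presentation rounding used throughout: published indicator tables round
#' halves up, whereas [base::round()] rounds halves to even. Internal
#' arithmetic is never rounded; this is applied only when formatting output.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(43.145, 2)  # 43.15
#' @export
round_half_up <- function(x, digits = 0) {
  check_numeric(x, "x", allow_na = TRUE)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Table conventions: rates and years at 2 dp, percentages and display ratios
# (x100) at 1 dp.
round_rate <- function(x) round_half_up(x, 2)
round_pct <- function(x) round_half_up(x, 1)

#' Convert years of life lost between display units
#'
#' YLL is stored in person-years; summary tables print it in units of
#' 100,000 person-years or millions of person-years.
#'
#' @param yll Numeric vector of person-years.
#' @param units One of `"years"` (no conversion), `"1e5"` (hundreds of
#'   thousands) or `"1e6"` (millions).
#' @return Converted numeric vector.
#' @examples
#' yll_in_units(15.24e6, "1e5")  # 152.4
#' yll_in_units(15.24e6, "1e6")  # 15.24
#' @export
yll_in_units <- function(yll, units = c("years", "1e5", "1e6")) {
  check_numeric(yll, "yll", allow_na = TRUE)
  units <- match.arg(units)
  switch(units, years = yll, `1e5` = yll / 1e5, `1e6` = yll / 1e6)
}
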