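# Closed-form stillbirth metrics.
#
# Two denominators are in circulation for the stillbirth rate: live births
# (SLBR = 1000 SB/LB, the ICD "fetal death ratio") and total births
# (STBR = 1000 SB/TB with TB = SB + LB, the "fetal death rate"). The two are
# linked by the exact identity
#
#   SLBR - STBR = SLBR * STBR / 1000 >= 0,
#
# which also yields the closed-form conversions in both directions. Because
# SLBR shares its denominator with the neonatal mortality rate
# (NMR = 1000 NM/LB), SLBR:NMR equals the count ratio SB:NM, which STBR:NMR
# does not. SLBR further drives the stillbirths-adjusted life expectancy
#
#   SALE = 1000 * LE / (1000 + SLBR),
#
# the life expectancy of total rather than live births, and the stillbirth
# burden YLL = (LE - SALE) * LB in person-years.
#
# All functions compute on unrounded values; rounding belongs to the
# presentation layer (see write_summary() and round_half_up()).

#' Still live-birth rate (SLBR)
#'
#' Stillbirths per 1000 live births: the stillbirth rate defined with the
#' same denominator as the neonatal mortality rate.
#'
#' @param counts A [birth_counts()] object.
#' @return Numeric vector, per 1000 live births, unrounded.
#' @examples
#' compute_slbr(birth_counts(45090, 1e6))  # 45.09
#' @export
compute_slbr <- function(counts) {
  counts <- as_birth_counts(counts)
  if (any(counts$live_births == 0)) {
    abort_domain(sprintf(
      "compute_slbr: live_births is zero at record %d; SLBR is undefined.",
      which(counts$live_births == 0)[1]))
  }
  1000 * counts$stillbirths / counts$live_births
}

#' Still total-birth rate (STBR)
#'
#' Stillbirths per 1000 total (still + live) births. Always below 1000 and
#' never above the SLBR of the same counts.
#'
#' @inheritParams compute_slbr
#' @return Numeric vector, per 1000 total births, unrounded.
#' @examples
#' compute_stbr(birth_counts(45090, 1e6))  # 43.145
#' @export
compute_stbr <- function(counts) {
  counts <- as_birth_counts(counts)
  tb <- total_births(counts)
  if (any(tb == 0)) {
    abort_domain(sprintf(
      "compute_stbr: total births are zero at record %d; STBR is undefined.",
      which(tb == 0)[1]))
  }
  1000 * counts$stillbirths / tb
}

#' Neonatal mortality rate (NMR)
#'
#' Neonatal deaths per 1000 live births.
#'
#' @inheritParams compute_slbr
#' @return Numeric vector, per 1000 live births, unrounded.
#' @export
compute_nmr <- function(counts) {
  counts <- as_birth_counts(counts)
  if (any(counts$live_births == 0)) {
    abort_domain(sprintf(
      "compute_nmr: live_births is zero at record %d; NMR is undefined.",
      which(counts$live_births == 0)[1]))
  }
  1000 * counts$neonatal_deaths / counts$live_births
}

#' Convert SLBR to STBR
#'
#' Closed-form conversion implied by the gap identity
#' `SLBR - STBR = SLBR * STBR / 1000`: `STBR = 1000 * SLBR / (1000 + SLBR)`.
#'
#' @param slbr Still live-birth rate per 1000 live births, non-negative.
#' @return STBR per 1000 total births.
#' @examples
#' slbr_to_stbr(45.09)  # 43.14
#' @seealso [stbr_to_slbr()] for the exact inverse.
#' @export
slbr_to_stbr <- function(slbr) {
  check_nonneg(slbr, "slbr")
  1000 * slbr / (1000 + slbr)
}

#' Convert STBR to SLBR
#'
#' Exact inverse of [slbr_to_stbr()]: `SLBR = 1000 * STBR / (1000 - STBR)`.
#' This is the headline conversion when published estimates denominated in
#' total births are restated per 1000 live births.
#'
#' @param stbr Still total-birth rate per 1000 total births, in `[0, 1000)`.
#' @return SLBR per 1000 live births.
#' @examples
#' stbr_to_slbr(43.15)  # 45.096
#' @export
stbr_to_slbr <- function(stbr) {
  check_nonneg(stbr, "stbr")
  if (any(stbr >= 1000)) {
    abort_domain("stbr_to_slbr: STBR must be below 1000 per 1000 (stillbirths cannot exceed total births).")
  }
  1000 * stbr / (1000 - stbr)
}

#' Gap between SLBR and STBR
#'
#' For an exactly consistent pair the difference equals
#' `slbr * stbr / 1000`; on published (rounded) pairs plain subtraction is
#' what the tables print.
#'
#' @param slbr,stbr Rates per 1000, non-negative.
#' @return `slbr - stbr`, per 1000.
#' @export
rate_gap <- function(slbr, stbr) {
  check_nonneg(slbr, "slbr")
  check_nonneg(stbr, "stbr")
  slbr - stbr
}

#' Live births implied by a neonatal mortality rate
#'
#' Inverts `NMR = 1000 * NM / LB` to recover the live-birth count from the
#' neonatal death count and rate — the standard derivation when an
#' indicator table publishes deaths and rate but not births. The result is
#' generally fractional and is deliberately not rounded.
#'
#' @param neonatal_deaths Neonatal death count(s), non-negative.
#' @param nmr Neonatal mortality rate per 1000 live births, positive.
#' @return Implied live-birth count(s), possibly fractional.
#' @examples
#' live_births_from_nmr(50, 25)  # 2000
#' @export
live_births_from_nmr <- function(neonatal_deaths, nmr) {
  check_nonneg(neonatal_deaths, "neonatal_deaths")
  check_nonneg(nmr, "nmr")
  if (any(nmr == 0 & neonatal_deaths > 0)) {
    abort_inconsistency(
      "live_births_from_nmr: NMR is zero but neonatal deaths are positive; the pair is inconsistent.")
  }
  if (any(nmr == 0)) {
    abort_domain(paste(
      "live_births_from_nmr: NMR is zero, so live births cannot be derived;",
      "supply live_births directly."))
  }
  1000 * neonatal_deaths / nmr
}

#' SLBR to NMR ratio
#'
#' Because both rates are per 1000 live births, this ratio equals the count
#' ratio SB:NM exactly. Stored dimensionless; tables print it multiplied by
#' 100 (so 0.835 appears as 83.5).
#'
#' @param slbr SLBR per 1000 live births.
#' @param nmr NMR per 1000 live births, positive.
#' @return Dimensionless ratio.
#' @export
ratio_slbr_nmr <- function(slbr, nmr) {
  check_nonneg(slbr, "slbr")
  check_nonneg(nmr, "nmr")
  if (any(nmr == 0)) {
    abort_domain("ratio_slbr_nmr: NMR must be positive.")
  }
  slbr / nmr
}

#' STBR to NMR ratio
#'
#' Equals `ratio_slbr_nmr * (LB / TB)`, hence never exceeds the SLBR:NMR
#' ratio — the two denominators differ, so this ratio does *not* equal the
#' count ratio SB:NM. `lb_share` (the live-birth share of total births) is
#' validated so callers are forced to acknowledge the denominator mismatch.
#'
#' @param stbr STBR per 1000 total births.
#' @param nmr NMR per 1000 live births, positive.
#' @param lb_share Live births as a fraction of total births, in `(0, 1]`.
#' @return Dimensionless ratio `stbr / nmr`.
#' @export
ratio_stbr_nmr <- function(stbr, nmr, lb_share) {
  check_nonneg(stbr, "stbr")
  check_nonneg(nmr, "nmr")
  check_numeric(lb_share, "lb_share")
  if (any(nmr == 0)) {
    abort_domain("ratio_stbr_nmr: NMR must be positive.")
  }
  if (any(lb_share <= 0 | lb_share > 1)) {
    abort_domain("ratio_stbr_nmr: lb_share must lie in (0, 1].")
  }
  stbr / nmr
}

#' Stillbirths-adjusted life expectancy (SALE)
#'
#' Life expectancy of total births: 1000 live births carry
#' `1000 * LE` expected person-years, and spreading them over
#' `1000 + SLBR` total births gives
#' `SALE = 1000 * LE / (1000 + SLBR)`. Equal to LE exactly when there are
#' no stillbirths, strictly below it otherwise, and strictly decreasing in
#' SLBR.
#'
#' @param le Life expectancy at birth of live births, in years, positive.
#' @param slbr SLBR per 1000 live births, non-negative.
#' @return SALE in years, unrounded.
#' @examples
#' compute_sale(71, 13)  # 70.09 — roughly one year lost to stillbirths
#' @export
compute_sale <- function(le, slbr) {
  check_numeric(le, "le")
  check_nonneg(slbr, "slbr")
  if (any(le <= 0)) {
    abort_domain("compute_sale: life expectancy must be positive.")
  }
  1000 * le / (1000 + slbr)
}

#' Life-expectancy decrement due to stillbirths
#'
#' The exact loss `LE - SALE = SLBR * LE / (1000 + SLBR)`, increasing in
#' both arguments: a higher stillbirth rate loses more years, and so does a
#' higher life expectancy, because each stillbirth then forgoes more years.
#'
#' @inheritParams compute_sale
#' @return Decrement in years, unrounded.
#' @export
le_decrement <- function(le, slbr) {
  check_numeric(le, "le")
  check_nonneg(slbr, "slbr")
  if (any(le <= 0)) {
    abort_domain("le_decrement: life expectancy must be positive.")
  }
  slbr * le / (1000 + slbr)
}

#' Years of life lost (DALY/YLL) attributable to stillbirths
#'
#' The usual YLL recipe (deaths times remaining life expectancy at death)
#' collapses for stillbirths, whose life expectancy is zero; instead the
#' burden is the per-live-birth life-expectancy decrement times the number
#' of live births: `YLL = (LE - SALE) * LB`, in person-years. Convert for
#' display with [yll_in_units()].
#'
#' @param le Life expectancy of live births, years.
#' @param sale Stillbirths-adjusted life expectancy, years; must not exceed
#'   `le`.
#' @param live_births Live-birth count(s), non-negative.
#' @return YLL in person-years.
#' @examples
#' stillbirth_yll(le = 66.38, sale = compute_sale(66.38, 45.09),
#'                live_births = 5.32e6) / 1e5  # ~152, Table-style units
#' @export
stillbirth_yll <- function(le, sale, live_births) {
  check_numeric(le, "le")
  check_nonneg(sale, "sale")
  check_nonneg(live_births, "live_births")
  if (any(sale > le + 1e-9)) {
    abort_inconsistency("stillbirth_yll: SALE exceeds LE; the pair is inconsistent.")
  }
  pmax(le - sale, 0) * live_births
}

#' Percentage change between two values
#'
#' @param old Baseline value, nonzero.
#' @param new New value.
#' @param magnitude_only If `TRUE`, return the absolute value (the
#'   "ignoring the negative signs" convention used when quoting
#'   reductions).
#' @return Percent change `100 * (new - old) / old`, signed unless
#'   `magnitude_only`.
#' @examples
#' pct_change(33.97, 25.28, magnitude_only = TRUE)  # 25.58 -> "25.6%"
#' @export
pct_change <- function(old, new, magnitude_only = FALSE) {
  check_numeric(old, "old")
  check_numeric(new, "new")
  if (any(old == 0)) {
    abort_domain("pct_change: baseline value is zero; percentage change is undefined.")
  }
  out <- 100 * (new - old) / old
  if (magnitude_only) abs(out) else out
}

#' Growth decomposition of NMR via SLBR and the SLBR:NMR ratio
#'
#' Since `SLBR:NMR = SLBR / NMR`, growth rates satisfy
#' `g(SLBR:NMR) = g(SLBR) - g(NMR)` exactly in log growth rates and to
#' first order in simple proportionate changes. Given SLBR at two dates
#' (`v0`, `v1`) and the SLBR:NMR ratio at the same dates (`w0`, `w1`), this
#' returns both the additive first-order NMR change
#' `g_nmr_additive = g_slbr - g_ratio` and the exact one
#' `g_nmr_exact = (1 + g_slbr) / (1 + g_ratio) - 1`. The two are reported
#' side by side and never silently substituted for one another: with
#' changes of tens of percent they can differ materially.
#'
#' @param v0,v1 SLBR at the base and comparison dates; `v0 > 0`.
#' @param w0,w1 SLBR:NMR ratio at the same dates; `w0 > 0`.
#' @return An object of class `growth_decomposition`: a list with
#'   proportionate (dimensionless) changes `g_slbr`, `g_ratio`,
#'   `g_nmr_additive`, `g_nmr_exact`.
#' @examples
#' growth_decomposition(v0 = 11.33, v1 = 7.40, w0 = 75.1, w1 = 101.5)
#' @export
growth_decomposition <- function(v0, v1, w0, w1) {
  check_numeric(v0, "v0"); check_numeric(v1, "v1")
  check_numeric(w0, "w0"); check_numeric(w1, "w1")
  if (any(v0 <= 0) || any(w0 <= 0)) {
    abort_domain("growth_decomposition: baseline values must be positive.")
  }
  g_slbr <- (v1 - v0) / v0
  g_ratio <- (w1 - w0) / w0
  structure(
    list(
      g_slbr = g_slbr,
      g_ratio = g_ratio,
      g_nmr_additive = g_slbr - g_ratio,
      g_nmr_exact = (1 + g_slbr) / (1 + g_ratio) - 1
    ),
    class = "growth_decomposition"
  )
}

#' @export
print.growth_decomposition <- function(x, ...) {
  cat("Growth decomposition (proportionate changes)\n")
  cat(sprintf("  g(SLBR)            : %+.1f%%\n", 100 * x$g_slbr))
  cat(sprintf("  g(SLBR:NMR)        : %+.1f%%\n", 100 * x$g_ratio))
  cat(sprintf("  g(NMR), additive   : %+.1f%%  (first-order identity)\n",
              100 * x$g_nmr_additive))
  cat(sprintf("  g(NMR), exact      : %+.1f%%  (ratio algebra)\n",
              100 * x$g_nmr_exact))
  invisible(x)
}
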