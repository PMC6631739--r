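#' Birth counts for one or more country-years
#'
#' Bundles the three raw annual counts every rate in the package is built
#' from: stillbirths (SB), live births (LB) and neonatal deaths (NM). Total
#' births (TB = SB + LB) is always derived, never stored, so the two can
#' never drift apart. Counts are modelled as non-negative reals rather than
#' integers: fractional counts arise legitimately when live births are
#' back-derived from a neonatal mortality rate (see
#' [live_births_from_nmr()]), and real-valued counts let the algebraic
#' identities between rates hold exactly.
#'
#' @param stillbirths Non-negative numeric vector of stillbirth counts.
#' @param live_births Non-negative numeric vector of live-birth counts.
#' @param neonatal_deaths Non-negative numeric vector of neonatal death
#'   counts; must not exceed `live_births` element-wise. Defaults to 0.
#' @return A tibble of class `birth_counts` with columns `stillbirths`,
#'   `live_births`, `neonatal_deaths`.
#' @examples
#' bc <- birth_counts(stillbirths = 45090, live_births = 1e6,
#'                    neonatal_deaths = 45090)
#' compute_slbr(bc)  # 45.09 per 1000 live births
#' @seealso [rate_set()], [total_births()]
#' @export
birth_counts <- function(stillbirths, live_births, neonatal_deaths = 0) {
  check_nonneg(stillbirths, "stillbirths")
  check_nonneg(live_births, "live_births")
  check_nonneg(neonatal_deaths, "neonatal_deaths")
  n <- max(length(stillbirths), length(live_births), length(neonatal_deaths))
  bad_len <- function(x) length(x) != n && length(x) != 1
  if (bad_len(stillbirths) || bad_len(live_births) || bad_len(neonatal_deaths)) {
    abort_domain("birth_counts fields must have equal length or length 1.")
  }
  out <- tibble::tibble(
    stillbirths = rep_len(as.double(stillbirths), n),
    live_births = rep_len(as.double(live_births), n),
    neonatal_deaths = rep_len(as.double(neonatal_deaths), n)
  )
  if (any(out$neonatal_deaths > out$live_births)) {
    i <- which(out$neonatal_deaths > out$live_births)[1]
    abort_inconsistency(sprintf(
      "neonatal_deaths (%g) exceeds live_births (%g) at record %d.",
      out$neonatal_deaths[i], out$live_births[i], i))
  }
  class(out) <- c("birth_counts", class(out))
  out
}

as_birth_counts <- function(x) {
  if (inherits(x, "birth_counts")) return(x)
  if (is.data.frame(x)) {
    need <- c("stillbirths", "live_births")
    if (!all(need %in% names(x))) {
      abort_domain("A counts data frame needs `stillbirths` and `live_births` columns.")
    }
    nm <- if ("neonatal_deaths" %in% names(x)) x$neonatal_deaths else 0
    return(birth_counts(x$stillbirths, x$live_births, nm))
  }
  abort_domain("`counts` must be a birth_counts object or a data frame.")
}

#' Total births (still + live)
#'
#' @param counts A [birth_counts()] object (or data frame with the same columns).
#' @return Numeric vector of total births.
#' @export
total_births <- function(counts) {
  counts <- as_birth_counts(counts)
  counts$stillbirths + counts$live_births
}

#' All rates for a set of birth counts
#'
#' Computes the three rates per 1000 and the stillbirth-to-neonatal-death
#' ratio in one pass: SLBR (per 1000 live births), STBR (per 1000 total
#' births), NMR (per 1000 live births) and SB:NM. The ratio is stored
#' dimensionless (0.835, say); summary writers multiply by 100 for display.
#'
#' @param counts A [birth_counts()] object.
#' @return A tibble with columns `slbr`, `stbr`, `nmr`, `sb_nm_ratio`.
#' @examples
#' rate_set(birth_counts(45090, 1e6, 45090))
#' @export
rate_set <- function(counts) {
  counts <- as_birth_counts(counts)
  if (any(counts$neonatal_deaths == 0)) {
    abort_domain(paste(
      "rate_set: neonatal_deaths is zero for some record, so the SB:NM ratio",
      "is undefined; degenerate inputs are errors, not NaNs."))
  }
  tibble::tibble(
    slbr = compute_slbr(counts),
    stbr = compute_stbr(counts),
    nmr = compute_nmr(counts),
    sb_nm_ratio = counts$stillbirths / counts$neonatal_deaths
  )
}

#' Life expectancy, SALE, decrement and YLL for country-years
#'
#' Convenience wrapper applying [compute_sale()], [le_decrement()] and
#' [stillbirth_yll()] to vectors of life expectancy and SLBR.
#'
#' @param le Life expectancy at birth of live births, in years.
#' @param slbr Still live-birth rate per 1000 live births.
#' @param live_births Optional live-birth counts; when supplied, YLL in
#'   person-years is included, otherwise the `yll` column is `NA`.
#' @return A tibble with columns `le`, `sale`, `decrement`, `yll`.
#' @examples
#' adjusted_expectancy(le = 71, slbr = 13)
#' @export
adjusted_expectancy <- function(le, slbr, live_births = NULL) {
  sale <- compute_sale(le, slbr)
  dec <- le_decrement(le, slbr)
  yll <- if (is.null(live_births)) {
    NA_real_
  } else {
    stillbirth_yll(le, sale, live_births)
  }
  tibble::tibble(le = as.double(le), sale = sale, decrement = dec, yll = yll)
}
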