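# Regional / income-group aggregation.
#
# A "panel" is a tibble of country-year records with columns country,
# region, income_group, year, stillbirths, live_births, neonatal_deaths,
# life_expectancy (+ optional iso3, live_births_derived). Group summaries
# follow the published-table conventions: rates are pooled from summed
# counts (not averaged over countries), while LE/SALE/decrement summaries
# are unweighted across member countries; dispersion is the coefficient of
# variation because group means differ.

#' Recognised MDG region labels
#'
#' Developed region, Southern Asia, Caucasus and Central Asia, Eastern
#' Asia, Latin America and Caribbean, North Africa and Middle East,
#' South-eastern Asia, Sub-Saharan Africa.
#'
#' @return Character vector of the eight region codes.
#' @export
mdg_regions <- function() {
  c("DR", "SA", "CCA", "EA", "LAC", "NAME", "SEA", "SSA")
}

#' Recognised income-group labels
#'
#' Two tiers: high plus upper-middle income ("richer") and lower-middle
#' plus low income ("poorer").
#'
#' @return Character vector of the two labels.
#' @export
income_groups <- function() {
  c("high+upper-middle", "lower-middle+low")
}

panel_columns <- function() {
  c("country", "region", "income_group", "year",
    "stillbirths", "live_births", "neonatal_deaths", "life_expectancy")
}

#' Validate a country-year panel
#'
#' Checks required columns, closed label sets and count invariants. Most
#' users get panels from [read_panel()] or [generate_panel()], which call
#' this internally.
#'
#' @param x A data frame of country-year records.
#' @return `x` as a tibble with class `country_panel`.
#' @export
as_country_panel <- function(x) {
  if (!is.data.frame(x)) abort_domain("A panel must be a data frame.")
  missing_cols <- setdiff(panel_columns(), names(x))
  if (length(missing_cols)) {
    abort_domain(sprintf("Panel is missing required columns: %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  bad_region <- setdiff(unique(x$region), mdg_regions())
  if (length(bad_region)) {
    abort_domain(sprintf("Unknown region label(s): %s. Expected one of %s.",
                         paste(bad_region, collapse = ", "),
                         paste(mdg_regions(), collapse = ", ")))
  }
  bad_income <- setdiff(unique(x$income_group), income_groups())
  if (length(bad_income)) {
    abort_domain(sprintf("Unknown income_group label(s): %s. Expected one of %s.",
                         paste(bad_income, collapse = ", "),
                         paste(income_groups(), collapse = ", ")))
  }
  # count invariants checked via the constructor
  birth_counts(x$stillbirths, x$live_births, x$neonatal_deaths)
  check_numeric(x$life_expectancy, "life_expectancy")
  if (!inherits(x, "country_panel")) class(x) <- c("country_panel", class(x))
  x
}

panel_counts <- function(records) {
  birth_counts(records$stillbirths, records$live_births,
               records$neonatal_deaths)
}

check_single_year <- function(records, what) {
  if (nrow(records) == 0) {
    abort_domain(sprintf("%s: empty record set.", what))
  }
  if (length(unique(records$year)) > 1) {
    abort_domain(sprintf(
      "%s: records span multiple years (%s); summarise one year at a time.",
      what, paste(sort(unique(records$year)), collapse = ", ")))
  }
  invisible(records)
}

#' Pooled rates for a group of countries
#'
#' Rates for the whole region or income group: computed from summed counts
#' across members, i.e. the live-birth-weighted mean of member SLBRs — not
#' the unweighted mean of country rates.
#'
#' @param records A single-year subset of a country panel.
#' @return A one-row tibble from [rate_set()] on the pooled counts.
#' @export
pooled_rates <- function(records) {
  records <- as_country_panel(records)
  check_single_year(records, "pooled_rates")
  rate_set(birth_counts(sum(records$stillbirths),
                        sum(records$live_births),
                        sum(records$neonatal_deaths)))
}

#' Mean, standard deviation and coefficient of variation
#'
#' Cross-country dispersion of an indicator. The standard deviation is the
#' sample SD (n − 1 denominator, the convention for a set of observed
#' countries); the coefficient of variation `100 * sd / mean` is the
#' dispersion measure of choice when group means differ.
#'
#' @param values Numeric vector of at least two country-level values.
#' @return Named list with `mean`, `sd`, `cv_percent`.
#' @examples
#' dispersion(c(10, 20, 40, 70))  # mean 35, sd 26.46, cv 75.6
#' @export
dispersion <- function(values) {
  check_numeric(values, "values")
  if (length(values) < 2) {
    abort_domain("dispersion: need at least two values.")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (m <= 0) {
    abort_domain("dispersion: mean is not positive; coefficient of variation is undefined.")
  }
  list(mean = m, sd = s, cv_percent = 100 * s / m)
}

#' Total stillbirth YLL for a group of countries
#'
#' Sum of per-country `(LE - SALE) * LB`, in person-years. A member whose
#' fields violate the metric preconditions aborts the aggregate with the
#' country named, rather than silently contaminating the total.
#'
#' @param records A single-year subset of a country panel.
#' @return Total YLL in person-years.
#' @export
group_yll <- function(records) {
  records <- as_country_panel(records)
  check_single_year(records, "group_yll")
  per_country <- vapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    tryCatch({
      slbr <- 1000 * row$stillbirths / row$live_births
      if (row$live_births == 0) abort_domain("live_births is zero")
      sale <- compute_sale(row$life_expectancy, slbr)
      stillbirth_yll(row$life_expectancy, sale, row$live_births)
    }, sbmetrics_error = function(e) {
      abort_domain(sprintf("group_yll: invalid record for %s (%s): %s",
                           row$country, row$year, conditionMessage(e)))
    })
  }, numeric(1))
  sum(per_country)
}

summarise_group <- function(records, key) {
  counts <- panel_counts(records)
  rates <- rate_set(counts)
  pooled <- pooled_rates(records)
  slbr <- rates$slbr
  ratio <- rates$sb_nm_ratio
  sale <- compute_sale(records$life_expectancy, slbr)
  dec <- records$life_expectancy - sale
  lb <- records$live_births
  disp_or_na <- function(v) {
    if (length(v) >= 2 && mean(v) > 0) dispersion(v) else
      list(mean = mean(v), sd = NA_real_, cv_percent = NA_real_)
  }
  d_slbr <- disp_or_na(slbr)
  d_ratio <- disp_or_na(ratio)
  d_dec <- disp_or_na(dec)
  tibble::tibble(
    group_key = key,
    year = records$year[1],
    n_countries = nrow(records),
    pooled_slbr = pooled$slbr,
    pooled_stbr = pooled$stbr,
    pooled_nmr = pooled$nmr,
    pooled_ratio = pooled$sb_nm_ratio,
    mean_slbr = d_slbr$mean,
    sd_slbr = d_slbr$sd,
    cv_slbr = d_slbr$cv_percent,
    mean_ratio = d_ratio$mean,
    sd_ratio = d_ratio$sd,
    cv_ratio = d_ratio$cv_percent,
    mean_le = mean(records$life_expectancy),
    mean_sale = mean(sale),
    mean_decrement = mean(dec),
    sd_decrement = d_dec$sd,
    cv_decrement = d_dec$cv_percent,
    wmean_le = stats::weighted.mean(records$life_expectancy, lb),
    wmean_sale = stats::weighted.mean(sale, lb),
    total_yll = group_yll(records)
  )
}

#' Group summaries of a panel
#'
#' One summary row per group and year: pooled rates (from summed counts),
#' unweighted means and dispersion of country rates and of LE / SALE /
#' decrement, live-birth-weighted LE and SALE under distinct `wmean_*`
#' names to keep the two aggregations unambiguous, and the YLL total. A
#' "World" row over all records is always appended.
#'
#' @param panel A country panel.
#' @param by Grouping: `"region"`, `"income"` or `"world"` (world only).
#' @return A tibble of `GroupSummary` rows, one per group and year.
#' @export
summarize_panel <- function(panel, by = c("region", "income", "world")) {
  panel <- as_country_panel(panel)
  by <- match.arg(by)
  if (nrow(panel) == 0) abort_domain("summarize_panel: empty panel.")
  key_col <- switch(by, region = "region", income = "income_group", world = NULL)
  out <- lapply(sort(unique(panel$year)), function(yr) {
    yr_panel <- panel[panel$year == yr, ]
    rows <- list()
    if (!is.null(key_col)) {
      for (key in sort(unique(yr_panel[[key_col]]))) {
        rows[[key]] <- summarise_group(yr_panel[yr_panel[[key_col]] == key, ], key)
      }
    }
    rows[["World"]] <- summarise_group(yr_panel, "World")
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Difference between two group summaries on one metric
#'
#' Signed difference `a - b` on a shared summary field, e.g. the developed
#' region vs Sub-Saharan Africa gap in mean LE or mean SALE.
#'
#' @param a,b One-row group summaries (rows of [summarize_panel()] output,
#'   or any lists sharing the field).
#' @param field Name of the metric to difference.
#' @return Numeric difference, sign preserved.
#' @examples
#' group_gap(list(mean_le = 79.31), list(mean_le = 60.33), "mean_le")  # 18.98
#' @export
group_gap <- function(a, b, field) {
  if (!is.character(field) || length(field) != 1) {
    abort_domain("group_gap: `field` must be a single metric name.")
  }
  if (!(field %in% names(a)) || !(field %in% names(b))) {
    abort_domain(sprintf("group_gap: field `%s` is not present in both summaries.", field))
  }
  av <- a[[field]]; bv <- b[[field]]
  if (!is.numeric(av) || !is.numeric(bv)) {
    abort_domain(sprintf("group_gap: field `%s` is not numeric.", field))
  }
  av - bv
}

#' Count countries passing a percentage-reduction threshold
#'
#' Pairs countries across two years and counts those whose indicator fell
#' by more than `min_reduction` percent (magnitude of the percentage
#' change; increases never qualify). Countries present in only one year
#' are skipped with a warning.
#'
#' @param records_t0,records_t1 Single-year panels for the base and
#'   comparison years.
#' @param metric `"nmr"` or `"slbr"` — computed from the counts.
#' @param min_reduction Qualifying threshold in percent (e.g. 40).
#' @return List with `count` (number of qualifiers) and `mean_reduction`
#'   (mean magnitude among qualifiers, `NA` when none qualify).
#' @export
threshold_count <- function(records_t0, records_t1,
                            metric = c("nmr", "slbr"), min_reduction) {
  metric <- match.arg(metric)
  records_t0 <- as_country_panel(records_t0)
  records_t1 <- as_country_panel(records_t1)
  check_single_year(records_t0, "threshold_count (base year)")
  check_single_year(records_t1, "threshold_count (comparison year)")
  check_numeric(min_reduction, "min_reduction")
  metric_fun <- switch(metric, nmr = compute_nmr, slbr = compute_slbr)
  unpaired <- c(setdiff(records_t0$country, records_t1$country),
                setdiff(records_t1$country, records_t0$country))
  if (length(unpaired)) {
    rlang::warn(sprintf("threshold_count: skipping %d unpaired countr%s: %s",
                        length(unpaired), if (length(unpaired) == 1) "y" else "ies",
                        paste(unpaired, collapse = ", ")))
  }
  common <- intersect(records_t0$country, records_t1$country)
  if (length(common) == 0) return(list(count = 0L, mean_reduction = NA_real_))
  t0 <- records_t0[match(common, records_t0$country), ]
  t1 <- records_t1[match(common, records_t1$country), ]
  v0 <- metric_fun(panel_counts(t0))
  v1 <- metric_fun(panel_counts(t1))
  change <- pct_change(v0, v1)
  qualifies <- change < 0 & abs(change) > min_reduction
  list(
    count = sum(qualifies),
    mean_reduction = if (any(qualifies)) mean(abs(change[qualifies])) else NA_real_
  )
}
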