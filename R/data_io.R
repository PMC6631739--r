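# Panel I/O: delimited text in, validated country_panel out; summary tables
# out with presentation rounding. Delimiter auto-detected between comma and
# tab; column names case-insensitive. Row-level failures never abort the
# read: valid rows are returned and every rejected row appears exactly once
# in the validation report with a machine-readable reason code.

required_input_columns <- function() {
  c("country", "region", "income_group", "year",
    "stillbirths", "neonatal_deaths", "neonatal_mortality_rate",
    "life_expectancy")
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(",")
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

new_error_report <- function() {
  tibble::tibble(row = integer(), country = character(),
                 field = character(), reason = character(),
                 message = character())
}

#' Read and validate a country-year panel
#'
#' Reads a CSV/TSV panel with required columns `country`, `region`,
#' `income_group`, `year`, `stillbirths`, `neonatal_deaths`,
#' `neonatal_mortality_rate`, `life_expectancy` and optional `iso3`,
#' `live_births` (names case-insensitive; delimiter auto-detected). When
#' `live_births` is absent it is derived from the neonatal death count and
#' rate via [live_births_from_nmr()] and the derivation is flagged in the
#' `live_births_derived` column. Rows failing validation are dropped —
#' never imputed — and reported with row numbers and reason codes in the
#' `validation` attribute (see [validation_report()]).
#'
#' @param path Path to a delimited text file.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @param group_config Optional path to a YAML file mapping country names
#'   to `region` / `income_group` labels, overriding the file's columns,
#'   e.g. `countries: {Pakistan: {region: SA, income_group: lower-middle+low}}`.
#' @return A `country_panel` tibble of the valid rows, with attribute
#'   `validation` holding the error report.
#' @export
read_panel <- function(path, delim = NULL, group_config = NULL) {
  if (!file.exists(path)) {
    abort_domain(sprintf("read_panel: file not found: %s", path))
  }
  delim <- delim %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(required_input_columns(), names(raw))
  if (length(missing_cols)) {
    abort_domain(sprintf("read_panel: missing required column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  errors <- new_error_report()
  if (nrow(raw) == 0) {
    out <- empty_panel()
    attr(out, "validation") <- errors
    return(out)
  }

  overrides <- NULL
  if (!is.null(group_config)) {
    cfg <- yaml::read_yaml(group_config)
    overrides <- cfg$countries
  }

  numeric_fields <- c("year", "stillbirths", "neonatal_deaths",
                      "neonatal_mortality_rate", "life_expectancy",
                      if ("live_births" %in% names(raw)) "live_births")
  has_lb <- "live_births" %in% names(raw)

  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    rec <- as.list(raw[i, ])
    country <- rec$country %||% NA_character_
    fail <- function(field, reason, msg) {
      errors <<- dplyr::bind_rows(errors, tibble::tibble(
        row = i, country = as.character(country), field = field,
        reason = reason, message = msg))
    }
    if (is.na(country) || !nzchar(country)) {
      fail("country", "missing_value", "country name is missing")
      next
    }
    num <- list(); bad <- FALSE
    for (f in numeric_fields) {
      v <- suppressWarnings(as.numeric(rec[[f]]))
      if (is.na(v) && !(f == "live_births" && (is.na(rec[[f]]) || !nzchar(rec[[f]])))) {
        fail(f, if (is.na(rec[[f]]) || !nzchar(rec[[f]] %||% "")) "missing_value" else "bad_numeric",
             sprintf("`%s` is not a usable number (got %s)", f,
                     rec[[f]] %||% "nothing"))
        bad <- TRUE
      }
      num[[f]] <- v
    }
    if (bad) next
    if (any(unlist(num[c("stillbirths", "neonatal_deaths",
                         "neonatal_mortality_rate", "life_expectancy")]) < 0)) {
      fail("counts", "negative_value", "counts and rates must be non-negative")
      next
    }
    if (overrides_has(overrides, country)) {
      ov <- overrides[[country]]
      if (!is.null(ov$region)) rec$region <- ov$region
      if (!is.null(ov$income_group)) rec$income_group <- ov$income_group
    }
    if (!(rec$region %in% mdg_regions())) {
      fail("region", "bad_region",
           sprintf("unknown region `%s`", rec$region %||% "NA"))
      next
    }
    if (!(rec$income_group %in% income_groups())) {
      fail("income_group", "bad_income_group",
           sprintf("unknown income group `%s`", rec$income_group %||% "NA"))
      next
    }
    lb <- if (has_lb && !is.na(num$live_births)) num$live_births else NA_real_
    lb_derived <- FALSE
    if (is.na(lb)) {
      if (num$neonatal_mortality_rate == 0) {
        if (num$neonatal_deaths > 0) {
          fail("neonatal_mortality_rate", "nmr_zero_inconsistent",
               "NMR is 0 but neonatal deaths are positive; cannot derive live births")
        } else {
          fail("neonatal_mortality_rate", "nmr_zero_undefined_lb",
               "NMR is 0 and no live_births column; supply live_births directly")
        }
        next
      }
      lb <- 1000 * num$neonatal_deaths / num$neonatal_mortality_rate
      lb_derived <- TRUE
    }
    if (lb <= 0) {
      fail("live_births", "nonpositive_live_births", "live births must be positive")
      next
    }
    if (num$neonatal_deaths > lb) {
      fail("neonatal_deaths", "nm_exceeds_lb",
           "neonatal deaths exceed live births")
      next
    }
    if (num$life_expectancy <= 0) {
      fail("life_expectancy", "nonpositive_le", "life expectancy must be positive")
      next
    }
    rows[[i]] <- tibble::tibble(
      country = country,
      iso3 = toupper(rec$iso3 %||% NA_character_),
      region = rec$region,
      income_group = rec$income_group,
      year = num$year,
      stillbirths = num$stillbirths,
      live_births = lb,
      neonatal_deaths = num$neonatal_deaths,
      life_expectancy = num$life_expectancy,
      live_births_derived = lb_derived
    )
  }
  kept <- dplyr::bind_rows(rows)
  out <- if (nrow(kept)) as_country_panel(kept) else empty_panel()
  if (nrow(errors)) {
    rlang::inform(sprintf("read_panel: %d of %d row(s) rejected; see validation_report().",
                          length(unique(errors$row)), nrow(raw)))
  }
  attr(out, "validation") <- errors
  out
}

overrides_has <- function(overrides, country) {
  !is.null(overrides) && country %in% names(overrides)
}

empty_panel <- function() {
  out <- tibble::tibble(
    country = character(), iso3 = character(), region = character(),
    income_group = character(), year = numeric(), stillbirths = numeric(),
    live_births = numeric(), neonatal_deaths = numeric(),
    life_expectancy = numeric(), live_births_derived = logical())
  class(out) <- c("country_panel", class(out))
  out
}

#' Validation report of a read panel
#'
#' @param panel Result of [read_panel()].
#' @return Tibble of rejected rows: `row`, `country`, `field`, `reason`
#'   (machine-readable code), `message`.
#' @export
validation_report <- function(panel) {
  attr(panel, "validation") %||% new_error_report()
}

#' Write a country panel as delimited text
#'
#' @param panel A country panel.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- as_country_panel(panel)
  out <- tibble::as_tibble(panel)
  out$neonatal_mortality_rate <- compute_nmr(panel_counts(panel))
  cols <- c("country", "iso3", "region", "income_group", "year",
            "stillbirths", "live_births", "neonatal_deaths",
            "neonatal_mortality_rate", "life_expectancy")
  cols <- intersect(cols, names(out))
  write_delim_by_ext(out[, cols], path)
}

write_delim_by_ext <- function(x, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tryCatch(
    readr::write_delim(x, path, delim = delim),
    error = function(e) abort_domain(sprintf("Failed writing %s: %s", path,
                                             conditionMessage(e))))
  invisible(path)
}

#' Write group summaries as a delimited table
#'
#' Applies the presentation conventions: rates and years rounded to 2 dp
#' (half up), percentages and display ratios to 1 dp, SB:NM ratios
#' multiplied by 100 for display, and YLL converted to the requested unit.
#' Column names carry their units so the header is self-describing.
#' Internal values are never rounded; use `round = FALSE` to write full
#' precision.
#'
#' @param summaries Output of [summarize_panel()].
#' @param path Output path (`.tsv` for tab-delimited), or `""` for stdout.
#' @param yll_units `"1e5"`, `"1e6"` or `"years"`.
#' @param round Apply presentation rounding (default `TRUE`).
#' @return The formatted tibble, invisibly (also written to `path`).
#' @export
write_summary <- function(summaries, path, yll_units = c("1e5", "1e6", "years"),
                          round = TRUE) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    abort_domain("write_summary: empty summaries.")
  }
  yll_units <- match.arg(yll_units)
  fmt <- format_summary(summaries, yll_units = yll_units, round = round)
  if (identical(path, "")) {
    cat(readr::format_delim(fmt, delim = ","))
  } else {
    write_delim_by_ext(fmt, path)
  }
  invisible(fmt)
}

format_summary <- function(summaries, yll_units = "1e5", round = TRUE) {
  x <- tibble::as_tibble(summaries)
  rate_cols <- intersect(c("pooled_slbr", "pooled_stbr", "pooled_nmr",
                           "mean_slbr", "sd_slbr", "mean_le", "mean_sale",
                           "mean_decrement", "sd_decrement",
                           "wmean_le", "wmean_sale"), names(x))
  ratio_cols <- intersect(c("pooled_ratio", "mean_ratio", "sd_ratio"), names(x))
  pct_cols <- intersect(c("cv_slbr", "cv_ratio", "cv_decrement"), names(x))
  for (cc in ratio_cols) x[[cc]] <- 100 * x[[cc]]  # display convention
  if ("total_yll" %in% names(x)) {
    x$total_yll <- yll_in_units(x$total_yll, yll_units)
  }
  if (round) {
    for (cc in rate_cols) x[[cc]] <- round_rate(x[[cc]])
    for (cc in c(ratio_cols, pct_cols)) x[[cc]] <- round_pct(x[[cc]])
    if ("total_yll" %in% names(x)) x$total_yll <- round_half_up(x$total_yll, 1)
  }
  unit_tag <- c(pooled_slbr = "per1000lb", pooled_stbr = "per1000tb",
                pooled_nmr = "per1000lb", mean_slbr = "per1000lb",
                sd_slbr = "per1000lb", pooled_ratio = "x100",
                mean_ratio = "x100", sd_ratio = "x100",
                cv_slbr = "pct", cv_ratio = "pct", cv_decrement = "pct",
                mean_le = "years", mean_sale = "years",
                mean_decrement = "years", sd_decrement = "years",
                wmean_le = "years", wmean_sale = "years",
                total_yll = switch(yll_units, `1e5` = "1e5py",
                                   `1e6` = "1e6py", years = "py"))
  names(x) <- vapply(names(x), function(nm) {
    if (nm %in% names(unit_tag)) paste0(nm, "_", unit_tag[[nm]]) else nm
  }, character(1))
  x
}
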