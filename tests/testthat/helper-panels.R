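# Fixtures built in code: small hand-constructed panels with exactly known
# rates, and a writer for temporary CSV inputs.

# Panel whose counts are chosen so SLBR/NMR/LE are round numbers.
tiny_panel <- function(year = 2015) {
  tibble::tibble(
    country = c("Alpha", "Beta", "Gamma", "Delta"),
    iso3 = c("AAA", "BBB", "CCC", "DDD"),
    region = c("DR", "EA", "SSA", "SA"),
    income_group = c("high+upper-middle", "high+upper-middle",
                     "lower-middle+low", "lower-middle+low"),
    year = year,
    stillbirths = c(500, 2000, 30000, 45000),
    live_births = c(1e5, 5e5, 1e6, 1.5e6),
    neonatal_deaths = c(600, 2500, 32000, 50000),
    life_expectancy = c(80, 76, 58, 64),
    live_births_derived = FALSE
  )
}

# A country-year row consistent with the published Pakistan cells: LB is
# back-solved from the printed YLL (152.4e5 person-years) and decrement,
# SB from the printed SLBR, and NM from an NMR of 45.5.
pakistan_row <- function() {
  lb <- 152.4e5 / (66.38 - compute_sale(66.38, 45.09))
  tibble::tibble(
    country = "Pakistan", iso3 = "PAK", region = "SA",
    income_group = "lower-middle+low", year = 2015,
    stillbirths = 45.09 * lb / 1000, live_births = lb,
    neonatal_deaths = 45.5 * lb / 1000, life_expectancy = 66.38,
    live_births_derived = FALSE)
}

write_panel_csv <- function(df, path = tempfile(fileext = ".csv"),
                            drop_live_births = FALSE) {
  out <- df
  out$neonatal_mortality_rate <- 1000 * out$neonatal_deaths / out$live_births
  if (drop_live_births) out$live_births <- NULL
  out$live_births_derived <- NULL
  readr::write_csv(out, path)
  path
}

random_counts <- function(n, seed) {
  set.seed(seed)
  birth_counts(
    stillbirths = stats::runif(n, 0, 6e4),
    live_births = stats::runif(n, 1e4, 5e6),
    neonatal_deaths = 0)
}
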