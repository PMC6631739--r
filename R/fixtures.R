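# Bundled reference tables: published 2015 (and 2000) stillbirth indicators
# as printed, used as oracles. Cells are literal published values, never
# recomputed here, so tests can distinguish "the package reproduces the
# published arithmetic" from "the package trusts the published numbers".

#' Reference table: ten countries with the highest stillbirth rates, 2015
#'
#' Printed SLBR, STBR (both per 1000) and their gap for the ten
#' highest-rate countries. Values are stored exactly as published (2 dp).
#'
#' @return A tibble with columns `country`, `slbr`, `stbr`, `gap`.
#' @export
ref_top10_rates <- function() {
  tibble::tribble(
    ~country,                    ~slbr,  ~stbr,  ~gap,
    "Pakistan",                  45.09,  43.15,  1.94,
    "Nigeria",                   44.81,  42.89,  1.92,
    "Chad",                      41.58,  39.92,  1.66,
    "Guinea-Bissau",             38.10,  36.70,  1.40,
    "Niger",                     38.07,  36.67,  1.40,
    "Somalia",                   36.80,  35.49,  1.31,
    "Djibouti",                  35.85,  34.61,  1.24,
    "Central African Republic",  35.59,  34.37,  1.22,
    "Togo",                      35.36,  34.15,  1.21,
    "Mali",                      33.63,  32.53,  1.10
  )
}

#' Reference table: SLBR and SLBR:NMR by region and income group
#'
#' Pooled SLBR (per 1000 live births) and SLBR:NMR ratio (x100), with
#' cross-country SD and SD/mean (percent), for the eight MDG regions, the
#' world, and the two income groups, in 2000 and 2015. `slbr` is the rate
#' for the whole group (pooled); `sd_*` / `cv_*` are across the member
#' countries.
#'
#' @return A tibble, one row per group and year.
#' @export
ref_group_rates <- function() {
  tibble::tribble(
    ~group,              ~year, ~slbr, ~ratio, ~sd_slbr, ~cv_slbr, ~sd_ratio, ~cv_ratio,
    "DR",                 2000,  4.51,   83.5,     2.21,     45.3,      54.7,      50.9,
    "DR",                 2015,  3.44,  107.0,     1.63,     46.9,      68.4,      49.1,
    "SA",                 2000, 36.76,   81.1,     15.8,     53.7,      14.9,      18.8,
    "SA",                 2015, 26.16,   89.7,     12.8,     65.2,      27.1,      28.2,
    "CCA",                2000, 17.14,   63.3,     4.85,     25.9,      26.3,      34.1,
    "CCA",                2015, 12.02,   74.5,     3.53,     27.5,      45.4,      43.9,
    "EA",                 2000, 14.47,   69.7,     7.14,     57.3,      27.7,      36.3,
    "EA",                 2015,  7.21,  128.9,     4.73,     62.3,      31.6,      29.2,
    "LAC",                2000, 11.40,   77.8,     5.64,     42.9,      37.3,      39.2,
    "LAC",                2015,  8.28,   89.3,     4.77,     46.2,      42.3,      39.1,
    "NAME",               2000, 20.28,   94.6,     8.91,     54.9,      36.9,      33.2,
    "NAME",               2015, 14.75,  114.1,     6.86,     57.7,      95.7,      61.0,
    "SEA",                2000, 17.28,   81.6,     7.22,     44.2,      37.6,      38.1,
    "SEA",                2015, 12.37,   90.9,     5.31,     41.9,      42.7,      39.6,
    "SSA",                2000, 36.92,   90.5,     10.2,     32.9,      19.7,      23.0,
    "SSA",                2015, 29.50,  103.2,     8.45,     34.7,      22.8,      24.2,
    "World",              2000, 25.37,   83.1,     12.5,     72.3,      38.5,      40.3,
    "World",              2015, 18.73,   97.7,     9.86,     75.5,      58.8,      50.3,
    "high+upper-middle",  2000, 11.33,   75.1,     6.43,     66.4,      46.5,      45.3,
    "high+upper-middle",  2015,  7.40,  101.5,     5.03,     69.7,      70.9,      54.4,
    "lower-middle+low",   2000, 33.97,   84.9,     11.1,     40.2,      19.5,      22.7,
    "lower-middle+low",   2015, 25.28,   97.0,     9.15,     43.2,      26.1,      26.7
  )
}

#' Reference table: largest life-expectancy decrements and stillbirth YLL, 2015
#'
#' Seventeen countries: the ten with the largest decrease in life
#' expectancy once stillbirths are counted (`panel = "decrement"`), and
#' seven more that complete the ten largest stillbirth-YLL totals
#' (`panel = "yll"`). LE and SALE in years; `yll_1e5` in units of 100,000
#' person-years (so India's 392.0 is 39.2 million years).
#'
#' @return A tibble with columns `country`, `panel`, `le`, `sale`,
#'   `decrement`, `yll_1e5`.
#' @export
ref_country_sale <- function() {
  tibble::tribble(
    ~country,            ~panel,      ~le,   ~sale, ~decrement, ~yll_1e5,
    "Pakistan",          "decrement", 66.38, 63.52,       2.86,    152.4,
    "Nigeria",           "decrement", 53.05, 50.77,       2.28,    159.1,
    "Niger",             "decrement", 61.97, 59.70,       2.27,     21.6,
    "Djibouti",          "decrement", 62.29, 60.13,       2.16,      0.5,
    "Chad",              "decrement", 51.87, 49.80,       2.07,     12.5,
    "Togo",              "decrement", 60.12, 58.07,       2.05,      5.1,
    "Guinea-Bissau",     "decrement", 55.47, 53.43,       2.04,      1.3,
    "Somalia",           "decrement", 55.69, 53.71,       1.98,      8.8,
    "Comoros",           "decrement", 63.55, 61.61,       1.94,      0.5,
    "Ethiopia",          "decrement", 64.58, 62.66,       1.92,     60.3,
    "India",             "yll",       68.35, 66.78,       1.57,    392.0,
    "China",             "yll",       75.99, 75.45,       0.54,     91.8,
    "Bangladesh",        "yll",       72.00, 70.17,       1.83,     58.1,
    "Congo, Dem. Rep.",  "yll",       59.02, 57.41,       1.61,     50.4,
    "Indonesia",         "yll",       69.07, 68.16,       0.91,     50.0,
    "Tanzania",          "yll",       65.49, 64.02,       1.47,     30.1,
    "Egypt, Arab Rep.",  "yll",       71.32, 70.45,       0.87,     24.4
  )
}

#' Reference table: LE, SALE, decrement and YLL by region and income group, 2015
#'
#' Unweighted group means of LE, SALE and the decrement (years), their
#' cross-country SD and SD/mean (percent), and the group YLL total. The
#' published YLL column header for this table reads "in 100,000", but the
#' accompanying narrative calls the world total "165.3 million years" and
#' the per-country table using the same header is internally consistent
#' with 100,000s; these group totals are therefore stored as millions
#' (`yll_millions`), treating the group-table header as a misprint.
#'
#' @return A tibble, one row per region/income group plus the world.
#' @export
ref_group_sale <- function() {
  tibble::tribble(
    ~group,              ~mean_le, ~mean_sale, ~mean_decrement, ~yll_millions, ~sd_le, ~sd_sale, ~sd_decrement, ~cv_le, ~cv_sale, ~cv_decrement,
    "DR",                   79.31,      79.04,            0.27,           3.6,    3.7,      3.7,          0.11,    4.6,      4.7,          41.8,
    "SA",                   70.53,      69.23,            1.30,          63.4,    5.1,      5.7,          0.79,    7.2,      8.2,          60.2,
    "CCA",                  70.89,      69.99,            0.89,           1.6,    3.1,      3.1,          0.23,    4.3,      4.5,          25.8,
    "EA",                   74.58,      74.03,            0.54,           9.7,    5.8,      6.0,          0.32,    7.7,      8.1,          57.9,
    "LAC",                  74.14,      73.40,            0.75,           6.7,    3.8,      4.0,          0.45,    5.1,      5.4,          41.6,
    "NAME",                 74.06,      73.21,            0.85,          10.4,    3.7,      4.0,          0.45,    5.0,      5.5,          52.3,
    "SEA",                  71.22,      70.34,            0.88,          10.6,    4.7,      5.0,          0.34,    6.6,      7.0,          38.9,
    "SSA",                  60.33,      58.92,            1.41,          59.4,    5.8,      6.0,          0.43,    9.7,     10.1,          30.8,
    "World",                71.18,      70.33,            0.85,         165.3,   8.38,     8.82,          0.56,   11.8,     12.5,          65.2,
    "high+upper-middle",    76.14,      75.63,            0.51,          27.2,    5.6,      5.9,          0.32,    7.4,      7.7,          62.5,
    "lower-middle+low",     64.69,      63.39,            1.30,         138.1,   6.83,     7.07,          0.48,   10.6,     11.1,          37.0
  )
}

#' All bundled reference tables
#'
#' @return Named list: `top10_rates`, `group_rates`, `country_sale`,
#'   `group_sale`. See the individual `ref_*` accessors for column notes.
#' @export
reference_tables <- function() {
  list(
    top10_rates = ref_top10_rates(),
    group_rates = ref_group_rates(),
    country_sale = ref_country_sale(),
    group_sale = ref_group_sale()
  )
}
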