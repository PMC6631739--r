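# Seeded synthetic country panels with the joint structure the metrics
# assume: two income tiers with disjoint SLBR ranges, an SB:NM ratio near
# 0.9, life expectancy declining in SLBR, and log-uniform live-birth
# counts. Counts are real-valued by default so every algebraic identity
# holds to machine precision; an integerize flag rounds them to expose the
# (small) gap between the algebra and genuine count data.

#' Configuration for the synthetic panel generator
#'
#' Defaults mirror the observed 2015 landscape: 194 countries split
#' between a richer tier (high + upper-middle income; SLBR roughly 2–15
#' per 1000) and a poorer tier (lower-middle + low income; SLBR roughly
#' 10–50), an SB:NM ratio centred at 0.9, baseline life expectancies of 78
#' (richer) and 62 (poorer) years falling 0.25 years per unit SLBR, and
#' live births log-uniform between 10^4 and 2x10^7. Between the two panel
#' years each country's SLBR declines multiplicatively: 34.7% in the
#' richer tier and 25.6% in the poorer, the observed pooled two-point
#' declines.
#'
#' @param n_countries Number of synthetic countries (default 194).
#' @param seed Integer seed; identical seed and config give a
#'   byte-identical panel.
#' @param tier_mix Fraction of countries in the poorer tier (default 0.5).
#' @param slbr_range_rich,slbr_range_poor Base-year SLBR intervals per
#'   1000 for the two tiers.
#' @param ratio_center,ratio_spread Mean and SD of the SB:NM ratio
#'   (normal, truncated below at 0.1 so that NMR = SLBR/ratio stays far
#'   below 1000 and neonatal deaths can never exceed live births).
#' @param le_base_rich,le_base_poor Tier baseline life expectancies, years.
#' @param le_slope Years of life expectancy lost per unit SLBR.
#' @param le_noise_sd SD of the Gaussian noise on life expectancy, years.
#' @param lb_range Live-birth interval, sampled log-uniformly.
#' @param years Two calendar years for the panel.
#' @param decline_rich,decline_poor Multiplicative SLBR decline between
#'   the two years per tier (proportions in `[0, 1)`).
#' @param integerize Round counts to integers (default `FALSE`; rounding
#'   breaks exact identities by up to 0.5/LB).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_countries = 194, seed = 1, tier_mix = 0.5,
                         slbr_range_rich = c(2, 15),
                         slbr_range_poor = c(10, 50),
                         ratio_center = 0.9, ratio_spread = 0.2,
                         le_base_rich = 78, le_base_poor = 62,
                         le_slope = 0.25, le_noise_sd = 1,
                         lb_range = c(1e4, 2e7),
                         years = c(2000, 2015),
                         decline_rich = 0.347, decline_poor = 0.256,
                         integerize = FALSE) {
  cfg <- list(n_countries = n_countries, seed = seed, tier_mix = tier_mix,
              slbr_range_rich = slbr_range_rich,
              slbr_range_poor = slbr_range_poor,
              ratio_center = ratio_center, ratio_spread = ratio_spread,
              le_base_rich = le_base_rich, le_base_poor = le_base_poor,
              le_slope = le_slope, le_noise_sd = le_noise_sd,
              lb_range = lb_range, years = years,
              decline_rich = decline_rich, decline_poor = decline_poor,
              integerize = integerize)
  ok_range <- function(r) length(r) == 2 && all(r > 0) && r[1] <= r[2]
  if (!is.numeric(n_countries) || n_countries < 0 ||
      n_countries != round(n_countries)) {
    abort_domain("synth_config: n_countries must be a non-negative integer.")
  }
  if (tier_mix < 0 || tier_mix > 1) {
    abort_domain("synth_config: tier_mix must lie in [0, 1].")
  }
  if (!ok_range(slbr_range_rich) || !ok_range(slbr_range_poor) ||
      !ok_range(lb_range)) {
    abort_domain("synth_config: ranges must be positive and ordered (low, high).")
  }
  if (ratio_center <= 0 || ratio_spread < 0) {
    abort_domain("synth_config: ratio_center must be positive and ratio_spread non-negative.")
  }
  if (le_base_rich <= 0 || le_base_poor <= 0 || le_noise_sd < 0) {
    abort_domain("synth_config: life-expectancy parameters must be positive (noise SD non-negative).")
  }
  if (length(years) != 2 || years[1] == years[2]) {
    abort_domain("synth_config: `years` must be two distinct calendar years.")
  }
  if (decline_rich < 0 || decline_rich >= 1 || decline_poor < 0 || decline_poor >= 1) {
    abort_domain("synth_config: declines must be proportions in [0, 1).")
  }
  structure(cfg, class = "synth_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  # rejection sampling; with the default centre 0.9 / sd 0.2 / lower 0.1
  # the acceptance rate is ~1, so this terminates immediately in practice
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= lower)) {
    k <- out <= lower
    out[k] <- stats::rnorm(sum(k), mean, sd)
  }
  out
}

#' Generate a synthetic country panel with ground truth
#'
#' For each country: draw the base-year SLBR uniformly within its tier
#' range and apply the tier's multiplicative decline for the second year;
#' draw an SB:NM ratio from the truncated normal and set NMR =
#' SLBR / ratio; draw live births log-uniformly; derive the stillbirth and
#' neonatal-death counts from the rates (real-valued, so the metric layer
#' recovers every latent rate exactly); and set life expectancy to the
#' tier baseline minus `le_slope` per unit SLBR plus Gaussian noise.
#' Richer-tier countries are assigned round-robin to regions DR, EA, LAC,
#' CCA and poorer-tier countries to SA, SSA, SEA, NAME.
#'
#' @param config A [synth_config()].
#' @return List with `panel` (a `country_panel`; two rows per country) and
#'   `truth` (tibble of every latent draw: tier, slbr, ratio, nmr,
#'   live_births, le).
#' @examples
#' sim <- generate_panel(synth_config(n_countries = 10, seed = 42))
#' max(abs(compute_slbr(sim$panel) - sim$truth$slbr))  # ~1e-14
#' @export
generate_panel <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) {
    abort_domain("generate_panel: `config` must come from synth_config().")
  }
  n <- config$n_countries
  if (n == 0) {
    return(list(panel = empty_panel(), truth = tibble::tibble(
      country = character(), year = numeric(), tier = character(),
      slbr = numeric(), ratio = numeric(), nmr = numeric(),
      live_births = numeric(), le = numeric())))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n_poor <- round(n * config$tier_mix)
  tier <- c(rep("poor", n_poor), rep("rich", n - n_poor))
  country <- sprintf("SYN%03d", seq_len(n))
  rich_regions <- c("DR", "EA", "LAC", "CCA")
  poor_regions <- c("SA", "SSA", "SEA", "NAME")
  region <- character(n)
  region[tier == "rich"] <- rep_len(rich_regions, sum(tier == "rich"))
  region[tier == "poor"] <- rep_len(poor_regions, sum(tier == "poor"))
  income <- ifelse(tier == "rich", "high+upper-middle", "lower-middle+low")

  lo <- ifelse(tier == "poor", config$slbr_range_poor[1], config$slbr_range_rich[1])
  hi <- ifelse(tier == "poor", config$slbr_range_poor[2], config$slbr_range_rich[2])
  slbr0 <- stats::runif(n, lo, hi)
  decline <- ifelse(tier == "poor", config$decline_poor, config$decline_rich)
  slbr1 <- slbr0 * (1 - decline)

  rows <- list()
  truth <- list()
  for (j in 1:2) {
    yr <- config$years[j]
    slbr <- if (j == 1) slbr0 else slbr1
    ratio <- rtrunc_norm(n, config$ratio_center, config$ratio_spread, 0.1)
    nmr <- slbr / ratio
    lb <- exp(stats::runif(n, log(config$lb_range[1]), log(config$lb_range[2])))
    le_base <- ifelse(tier == "rich", config$le_base_rich, config$le_base_poor)
    le <- le_base - config$le_slope * slbr + stats::rnorm(n, 0, config$le_noise_sd)
    le <- pmax(le, 20)  # guard against absurd noise draws
    sb <- slbr * lb / 1000
    nm <- nmr * lb / 1000
    if (config$integerize) {
      lb <- round(lb); sb <- round(sb); nm <- round(nm)
    }
    rows[[j]] <- tibble::tibble(
      country = country, iso3 = NA_character_, region = region,
      income_group = income, year = yr, stillbirths = sb,
      live_births = lb, neonatal_deaths = nm, life_expectancy = le,
      live_births_derived = FALSE)
    truth[[j]] <- tibble::tibble(
      country = country, year = yr, tier = tier, slbr = slbr,
      ratio = ratio, nmr = nmr, live_births = lb, le = le)
  }
  panel <- as_country_panel(dplyr::bind_rows(rows))
  list(panel = panel, truth = dplyr::bind_rows(truth))
}

#' Scale one field of a panel
#'
#' Returns a modified copy with `stillbirths` or `life_expectancy`
#' multiplied by a positive factor; the input panel is untouched. Useful
#' for exploring monotonicity: halving stillbirths halves the SLBR, and
#' raising life expectancy with stillbirths fixed raises the YLL.
#'
#' @param panel A country panel.
#' @param field `"stillbirths"` or `"life_expectancy"`.
#' @param multiplier Positive scale factor.
#' @return The perturbed panel.
#' @export
perturb_panel <- function(panel, field, multiplier) {
  panel <- as_country_panel(panel)
  if (!is.character(field) || length(field) != 1 ||
      !(field %in% c("stillbirths", "life_expectancy"))) {
    abort_domain("perturb_panel: `field` must be \"stillbirths\" or \"life_expectancy\".")
  }
  check_numeric(multiplier, "multiplier")
  if (multiplier <= 0) {
    abort_domain("perturb_panel: `multiplier` must be positive.")
  }
  panel[[field]] <- panel[[field]] * multiplier
  panel
}
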