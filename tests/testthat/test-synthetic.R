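# Synthetic panel generator: determinism, ground-truth recovery, tier
# structure and perturbation semantics.

test_that("config validation rejects malformed settings before any draw", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_countries = -1), class = "sbmetrics_domain_error")
  expect_error(synth_config(tier_mix = 1.2), class = "sbmetrics_domain_error")
  expect_error(synth_config(slbr_range_rich = c(15, 2)),
               class = "sbmetrics_domain_error")
  expect_error(synth_config(ratio_center = 0), class = "sbmetrics_domain_error")
  expect_error(synth_config(years = c(2015, 2015)),
               class = "sbmetrics_domain_error")
  expect_error(synth_config(decline_poor = 1), class = "sbmetrics_domain_error")
  expect_error(generate_panel(list()), class = "sbmetrics_domain_error")
})

test_that("zero countries gives an empty panel", {
  sim <- generate_panel(synth_config(n_countries = 0))
  expect_equal(nrow(sim$panel), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("identical seeds reproduce the panel; different seeds do not", {
  a <- generate_panel(synth_config(n_countries = 15, seed = 5))
  b <- generate_panel(synth_config(n_countries = 15, seed = 5))
  c <- generate_panel(synth_config(n_countries = 15, seed = 6))
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  expect_false(isTRUE(all.equal(a$panel$stillbirths, c$panel$stillbirths)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(generate_panel(synth_config(n_countries = 5, seed = 99)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("metric layer recovers every latent rate from generated counts", {
  sim <- generate_panel(synth_config(n_countries = 30, seed = 17))
  counts <- birth_counts(sim$panel$stillbirths, sim$panel$live_births,
                         sim$panel$neonatal_deaths)
  ord <- order(sim$panel$country, sim$panel$year)
  tru <- sim$truth[order(sim$truth$country, sim$truth$year), ]
  expect_equal(compute_slbr(counts)[ord], tru$slbr, tolerance = 1e-9)
  expect_equal(compute_nmr(counts)[ord], tru$nmr, tolerance = 1e-9)
  expect_equal(rate_set(counts)$sb_nm_ratio[ord], tru$ratio, tolerance = 1e-9)
  expect_equal(sim$panel$life_expectancy[ord], tru$le)
})

test_that("draws respect the configured structure", {
  cfg <- synth_config(n_countries = 40, seed = 2)
  sim <- generate_panel(cfg)
  tru <- sim$truth
  base <- tru[tru$year == cfg$years[1], ]
  rich <- base[base$tier == "rich", ]
  poor <- base[base$tier == "poor", ]
  expect_true(all(rich$slbr >= cfg$slbr_range_rich[1] &
                  rich$slbr <= cfg$slbr_range_rich[2]))
  expect_true(all(poor$slbr >= cfg$slbr_range_poor[1] &
                  poor$slbr <= cfg$slbr_range_poor[2]))
  expect_true(all(tru$ratio > 0))
  expect_true(all(sim$panel$neonatal_deaths <= sim$panel$live_births))
  # second-year SLBR is the base-year draw shrunk by the tier decline
  late <- tru[tru$year == cfg$years[2], ]
  decline <- ifelse(base$tier == "poor", cfg$decline_poor, cfg$decline_rich)
  expect_equal(late$slbr[match(base$country, late$country)],
               base$slbr * (1 - decline))
})

test_that("poorer-tier pooled SLBR exceeds richer-tier pooled SLBR", {
  for (seed in 1:5) {
    sim <- generate_panel(synth_config(n_countries = 20, seed = seed))
    p <- sim$panel[sim$panel$year == 2015, ]
    poor <- pooled_rates(p[p$income_group == "lower-middle+low", ])
    rich <- pooled_rates(p[p$income_group == "high+upper-middle", ])
    expect_gt(poor$slbr, rich$slbr)
  }
})

test_that("integerized counts relax identities by at most 0.5 per live birth", {
  sim <- generate_panel(synth_config(n_countries = 20, seed = 4,
                                     integerize = TRUE))
  expect_true(all(sim$panel$stillbirths == round(sim$panel$stillbirths)))
  counts <- birth_counts(sim$panel$stillbirths, sim$panel$live_births,
                         sim$panel$neonatal_deaths)
  ord <- order(sim$panel$country, sim$panel$year)
  tru <- sim$truth[order(sim$truth$country, sim$truth$year), ]
  tol <- 1000 * 0.5 / sim$panel$live_births[ord] + 1e-6 * tru$slbr
  expect_true(all(abs(compute_slbr(counts)[ord] - tru$slbr) <= tol))
})

test_that("perturbation scales one field and leaves the original alone", {
  sim <- generate_panel(synth_config(n_countries = 6, seed = 9))
  p <- sim$panel[sim$panel$year == 2015, ]
  expect_equal(perturb_panel(p, "stillbirths", 1), p)

  half <- perturb_panel(p, "stillbirths", 0.5)
  expect_equal(compute_slbr(birth_counts(half$stillbirths, half$live_births)),
               compute_slbr(birth_counts(p$stillbirths, p$live_births)) / 2)
  expect_equal(p$stillbirths, sim$panel$stillbirths[sim$panel$year == 2015])

  # raising LE with stillbirths fixed raises the YLL total
  taller <- perturb_panel(p, "life_expectancy", 1.1)
  expect_gt(group_yll(taller), group_yll(p))

  expect_error(perturb_panel(p, "live_births", 2),
               class = "sbmetrics_domain_error")
  expect_error(perturb_panel(p, "stillbirths", 0),
               class = "sbmetrics_domain_error")
})
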