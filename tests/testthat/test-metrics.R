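# Rate definitions, conversions, SALE/YLL arithmetic and trend helpers,
# frozen against hand-derived values and published table cells.

test_that("rate definitions give per-1000 values from raw counts", {
  expect_equal(compute_slbr(birth_counts(0, 12345)), 0)
  expect_equal(compute_slbr(birth_counts(13, 1000)), 13)
  expect_equal(compute_slbr(birth_counts(45090, 1e6)), 45.09)

  expect_equal(compute_stbr(birth_counts(0, 999)), 0)
  expect_equal(compute_stbr(birth_counts(777, 777)), 500)  # SB = LB
  # 1000 * 45090 / 1045090, by hand
  expect_equal(compute_stbr(birth_counts(45090, 1e6)), 43.14461, tolerance = 1e-6)

  expect_equal(compute_nmr(birth_counts(0, 1000, 0)), 0)
  expect_equal(compute_nmr(birth_counts(0, 1000, 30)), 30)

  # equal SB and NM counts force an SB:NM ratio of exactly 1
  rs <- rate_set(birth_counts(45090, 1e6, 45090))
  expect_equal(rs$nmr, 45.09)
  expect_equal(rs$sb_nm_ratio, 1)
})

test_that("rate definitions reject zero denominators, naming the record", {
  expect_error(compute_slbr(birth_counts(c(1, 5), c(10, 0))),
               "record 2", class = "sbmetrics_domain_error")
  expect_error(compute_stbr(birth_counts(0, 0)),
               class = "sbmetrics_domain_error")
  expect_error(compute_nmr(birth_counts(1, 0, 0)),
               class = "sbmetrics_domain_error")
  expect_error(birth_counts(1, 100, 200), class = "sbmetrics_inconsistency_error")
  expect_error(birth_counts(-1, 100), class = "sbmetrics_domain_error")
})

test_that("SLBR <-> STBR conversions match published top-rate rows", {
  expect_equal(slbr_to_stbr(0), 0)
  expect_equal(stbr_to_slbr(0), 0)
  # closed form agrees with the counts route
  expect_equal(slbr_to_stbr(45.09), compute_stbr(birth_counts(45.09, 1000)))
  expect_equal(round_half_up(slbr_to_stbr(41.58), 2), 39.92)  # Chad row
  # published Pakistan pair is rounded from unrounded inputs, so the
  # conversion of the rounded SLBR lands within one ulp of the printed STBR
  expect_equal(slbr_to_stbr(45.09), 43.15, tolerance = 0.01 / 43.15)
  expect_equal(stbr_to_slbr(43.15), 45.09, tolerance = 0.01 / 45.09)
  expect_error(slbr_to_stbr(-1), class = "sbmetrics_domain_error")
  expect_error(stbr_to_slbr(1000), class = "sbmetrics_domain_error")
})

test_that("rate gap reproduces printed row differences", {
  expect_equal(rate_gap(0, 0), 0)
  expect_equal(rate_gap(45.09, 43.15), 1.94)  # Pakistan
  expect_equal(rate_gap(38.10, 36.70), 1.40)  # Guinea-Bissau
})

test_that("live births are recovered from neonatal deaths and NMR", {
  expect_equal(live_births_from_nmr(0, 7.5), 0)
  expect_equal(live_births_from_nmr(50, 25), 2000)
  expect_equal(live_births_from_nmr(1000, 7.5), 133333.3333, tolerance = 1e-9)
  expect_error(live_births_from_nmr(10, 0),
               class = "sbmetrics_inconsistency_error")
  expect_error(live_births_from_nmr(0, 0), "supply live_births",
               class = "sbmetrics_domain_error")
})

test_that("SLBR:NMR equals SB:NM while STBR:NMR is shrunk by the LB share", {
  expect_equal(ratio_slbr_nmr(30, 30), 1)
  # world 2015: printed ratio 97.7 (x100) alongside SLBR 18.73
  expect_equal(round_half_up(100 * ratio_slbr_nmr(18.73, 18.73 / 0.977), 1), 97.7)
  # consistent counts: the two ratios differ exactly by LB/TB
  bc <- birth_counts(45090, 1e6, 45090)
  lb_share <- 1e6 / total_births(bc)
  r2 <- ratio_slbr_nmr(compute_slbr(bc), compute_nmr(bc))
  r3 <- ratio_stbr_nmr(compute_stbr(bc), compute_nmr(bc), lb_share)
  expect_equal(r3, r2 * lb_share)
  expect_lt(r3, r2)
  # SB = NM with live births half of total births
  expect_equal(ratio_stbr_nmr(stbr = 500, nmr = 1000, lb_share = 0.5), 0.5)
  expect_error(ratio_slbr_nmr(10, 0), class = "sbmetrics_domain_error")
  expect_error(ratio_stbr_nmr(10, 5, lb_share = 1.5),
               class = "sbmetrics_domain_error")
})

test_that("SALE and the decrement reproduce the worked example and table rows", {
  expect_equal(compute_sale(71, 0), 71)
  expect_equal(compute_sale(71, 13), 71000 / 1013)
  expect_equal(round_half_up(compute_sale(71, 13)), 70)

  # country rows: SALE from LE and SLBR at 2 dp
  expect_equal(round_half_up(compute_sale(66.38, 45.09), 2), 63.52)  # Pakistan
  expect_equal(round_half_up(compute_sale(53.05, 44.81), 2), 50.77)  # Nigeria
  expect_equal(round_half_up(compute_sale(51.87, 41.58), 2), 49.80)  # Chad

  expect_equal(le_decrement(80, 0), 0)
  expect_equal(round_half_up(le_decrement(53.05, 44.81), 2), 2.28)
  expect_equal(round_half_up(le_decrement(51.87, 41.58), 2), 2.07)
  expect_error(compute_sale(-1, 10), class = "sbmetrics_domain_error")
  expect_error(le_decrement(70, -2), class = "sbmetrics_domain_error")
})

test_that("stillbirth YLL is decrement times live births, in person-years", {
  expect_equal(stillbirth_yll(70, 70, 1e6), 0)
  expect_equal(stillbirth_yll(61, 60, 1e5), 1e5)  # 1.0 in 1e5 units
  # Pakistan: LB back-solved from printed YLL 152.4 (1e5) and decrement
  lb <- 152.4e5 / le_decrement(66.38, 45.09)
  sale <- compute_sale(66.38, 45.09)
  expect_equal(yll_in_units(stillbirth_yll(66.38, sale, lb), "1e5"), 152.4)
  expect_equal(yll_in_units(stillbirth_yll(66.38, sale, lb), "1e6"), 15.24)
  expect_error(stillbirth_yll(60, 61, 1e5),
               class = "sbmetrics_inconsistency_error")
})

test_that("pct_change matches the published trend arithmetic", {
  expect_equal(pct_change(10, 10), 0)
  # poorer-group SLBR reduction and ratio increase, 1 dp
  expect_equal(round_half_up(pct_change(33.97, 25.28, magnitude_only = TRUE), 1), 25.6)
  expect_equal(round_half_up(pct_change(84.9, 97.0), 1), 14.3)
  expect_equal(pct_change(10, 5), -50)
  expect_equal(pct_change(10, 5, magnitude_only = TRUE), 50)
  expect_error(pct_change(0, 5), class = "sbmetrics_domain_error")
})

test_that("growth decomposition reports additive and exact NMR changes", {
  g0 <- growth_decomposition(10, 10, 2, 2)
  expect_equal(g0$g_slbr, 0)
  expect_equal(g0$g_ratio, 0)
  expect_equal(g0$g_nmr_additive, 0)
  expect_equal(g0$g_nmr_exact, 0)

  # richer group, published two-point cells
  g <- growth_decomposition(v0 = 11.33, v1 = 7.40, w0 = 75.1, w1 = 101.5)
  expect_equal(round_half_up(100 * abs(g$g_slbr), 1), 34.7)
  expect_equal(g$g_nmr_additive, g$g_slbr - g$g_ratio)
  expect_equal(g$g_nmr_exact, (1 + g$g_slbr) / (1 + g$g_ratio) - 1)
  # first-order and exact versions differ materially at these magnitudes
  expect_equal(round_half_up(100 * g$g_nmr_additive, 1), -69.8)
  expect_equal(round_half_up(100 * g$g_nmr_exact, 1), -51.7)
  expect_error(growth_decomposition(0, 1, 2, 3),
               class = "sbmetrics_domain_error")
})

test_that("adjusted_expectancy bundles LE, SALE, decrement and YLL", {
  adj <- adjusted_expectancy(le = 71, slbr = 13, live_births = 1e6)
  expect_equal(adj$sale, compute_sale(71, 13))
  expect_equal(adj$decrement, adj$le - adj$sale)
  expect_equal(adj$yll, le_decrement(71, 13) * 1e6)
  expect_true(is.na(adjusted_expectancy(71, 13)$yll))
})
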