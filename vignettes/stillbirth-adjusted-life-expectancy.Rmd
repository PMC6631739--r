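---
title: "Stillbirth rates, adjusted life expectancy, and years of life lost: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stillbirth rates, adjusted life expectancy, and years of life lost: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmetrics)
```

## The problem

A stillbirth — fetal death at 28 or more completed weeks of gestation — is
recorded under two incompatible rate conventions. The ICD "fetal death
ratio" divides stillbirths (SB) by live births (LB); the "fetal death
rate" divides by total births (TB = SB + LB). `sbmetrics` names the two by
their denominators — still live-birth rate, SLBR = 1000·SB/LB, and still
total-birth rate, STBR = 1000·SB/TB — and treats the choice as
consequential rather than cosmetic: only SLBR shares its denominator with
the neonatal mortality rate (NMR = 1000·NM/LB), so only SLBR:NMR equals
the count ratio SB:NM, and only SLBR plugs directly into the
life-expectancy adjustment below. Global stillbirth estimates are
published as STBR, so restating them per 1000 live births is the package's
headline conversion.

## The model

Three exact algebraic facts drive everything:

1. **Gap identity.** From the definitions,
   `SLBR − STBR = SLBR · STBR / 1000 ≥ 0`, with equality only when there
   are no stillbirths. This yields closed-form conversions in both
   directions, `STBR = 1000·SLBR/(1000 + SLBR)` and
   `SLBR = 1000·STBR/(1000 − STBR)`, which are exact inverses. The gap
   grows with the rate itself, so the denominator choice matters most
   exactly where stillbirth burdens are highest.

2. **Stillbirths-adjusted life expectancy (SALE).** A cohort of 1000 live
   births embodies `1000 · LE` expected person-years. Spreading those
   person-years over the `1000 + SLBR` total births that produced the
   cohort gives the life expectancy of total births,

   `SALE = 1000 · LE / (1000 + SLBR)`,

   with decrement `LE − SALE = SLBR · LE / (1000 + SLBR)`, increasing in
   both arguments. For LE = 71 years and SLBR = 13 the adjustment divides
   71,000 person-years by 1013 births: about 70 years, i.e. roughly one
   year of headline life expectancy is conceded merely by counting the
   stillborn in the denominator.

3. **Years of life lost.** The usual YLL recipe (deaths × remaining life
   expectancy at the age of death) degenerates for stillbirths, whose life
   expectancy is zero. Instead the stillbirth burden is the per-live-birth
   decrement scaled by the cohort: `YLL = (LE − SALE) · LB`, in
   person-years.

For two-point trends the package decomposes NMR growth through the ratio:
since SLBR:NMR = SLBR/NMR, log growth rates satisfy
`log g(ratio) = log g(SLBR) − log g(NMR)` exactly, while simple
proportionate changes satisfy `g(NMR) ≈ g(SLBR) − g(ratio)` only to first
order. `growth_decomposition()` therefore always reports both the additive
first-order value and the exact value `(1+g_SLBR)/(1+g_ratio) − 1`,
clearly labelled; with changes of 25–35% the two differ by well over ten
percentage points, so silently substituting one for the other would be
misleading.

## Aggregation conventions

Group summaries follow the conventions of published indicator tables:

* **Pooled rates** are computed from summed counts
  (`1000 · ΣSB / ΣLB`), equivalently the live-birth-weighted mean of
  member SLBRs — never the unweighted mean of country rates.
* **LE, SALE and decrement summaries** are unweighted means across member
  countries; live-birth-weighted variants are exposed under distinct
  `wmean_*` names so the two aggregations cannot be confused.
* **Dispersion** is the coefficient of variation, `100 · sd/mean`, because
  group means differ widely. The SD is the *sample* SD (n − 1). The
  convention is not dictated by the quantities themselves; n − 1 is the
  usual choice for a set of observed countries and is stated here
  prominently because group-level SD cells in the bundled reference tables
  cannot adjudicate it (the underlying country lists live in source
  supplements not shipped here).
* **YLL totals** are plain sums over members, so they are additive over
  any partition and permutation-invariant — properties the test suite
  checks against brute-force accumulation.

Countries with invalid fields are excluded from summaries with a counted,
reported rejection — never imputed; a degenerate record (zero live births,
zero NMR alongside positive deaths) raises an error naming the country
rather than propagating NaN into a group total.

## Numerical and presentation choices

All internal arithmetic is on unrounded doubles. Rounding happens only at
the presentation layer: rates and years to 2 decimal places, percentages
and display ratios to 1, using round-half-away-from-zero
(`round_half_up()`) since indicator tables round halves up while R's
`round()` rounds halves to even. The SB:NM ratio is stored dimensionless
and multiplied by 100 only for display (so 0.835 prints as 83.5). YLL is
stored in person-years with display units of 100,000s or millions.

Published tables are themselves rounded from unrounded inputs, which has
one visible consequence the package deliberately does not paper over:
converting a 2-dp SLBR can land one unit of the last printed digit away
from the 2-dp STBR printed beside it, because up to ±0.005 of input
rounding propagates through the conversion. Tests that compare conversions
of printed values against printed values allow exactly that one-ulp slack
and no more; conversions of exact values are tested to 1e−9.

Counts are modelled as non-negative *reals*, not integers. Fractional
counts arise naturally when live births are back-derived from the neonatal
death count and rate (`LB = 1000 · NM / NMR`, the standard derivation when
an indicator extract omits births), and real-valued counts let every
identity above hold to machine precision.

One known misprint in the source material is asserted rather than patched:
the richer income group's SLBR:NMR ratio rises from 75.1 to 101.5 across
the two reference years, a difference of 26.4 and an increase of 35.2% at
1 dp, while the published narrative quotes the difference as 25.6 — a
value that reproduces neither the difference of the printed cells nor the
percentage printed beside it (25.6/75.1 would be 34.1%). The test suite
pins all three numbers so the discrepancy cannot be silently "fixed" in
either direction. Similarly, the group-level YLL table's column header
says "in 100,000" while its world total is described as 165.3 *million*
years and the analogous per-country table is internally consistent with
100,000s; the bundled group table stores those totals as millions and says
so in its documentation.

## The synthetic generator

`generate_panel()` emulates the joint structure the metrics assume, at the
scale of the real study conditions: 194 countries split between a richer
tier (SLBR drawn uniformly in 2–15 per 1000; baseline LE 78 years) and a
poorer tier (SLBR 10–50; baseline LE 62), an SB:NM ratio drawn from a
normal centred at 0.9 with SD 0.2, live births log-uniform between 10⁴ and
2×10⁷, LE declining 0.25 years per unit SLBR with 1 year of Gaussian
noise, and per-tier multiplicative SLBR declines of 34.7% (richer) and
25.6% (poorer) between the two panel years — the observed pooled two-point
declines. The ratio draw is truncated below at 0.1 so that
NMR = SLBR/ratio stays far below 1000 and neonatal deaths can never exceed
live births by construction. Tier mix defaults to one half in the absence
of a stated split.

Because counts are real-valued, the metric layer recovers every latent
rate from the generated counts to 1e−9, which is what makes the generator
usable as ground truth for property tests; an `integerize` option rounds
the counts and documents the resulting gap (up to 0.5/LB per rate) between
the algebra and genuine count data. LE is linked to SLBR linearly with
noise: the linear-with-noise form is the minimal structure supporting the
monotonicity checks and claims no distributional fidelity. The generator
is seeded and restores the caller's RNG state; identical seed and
configuration give a byte-identical panel.

What passing tests on synthetic panels do **not** show: the generator has
no within-country structure, no gestational-age or cause-of-death detail,
no reporting error (the very misclassification between stillbirths and
first-day neonatal deaths that motivates SALE), and no correlation between
live births and rates. Results on real panels inherit none of those
guarantees; the validation layer in `read_panel()` is what stands between
real data and the algebra.

## Problem sizes

The test suite exercises grids of a few thousand points (LE 40–90 ×
SLBR 0–60), 1000-draw random count sets, and synthetic panels of 6–40
countries; the full suite and the acceptance script each run in a few
seconds on one CPU. These sizes were chosen as comfortably sufficient for
the identities being checked, all of which are closed-form.

## Limitations

* No uncertainty propagation: the upstream estimates ship without
  intervals here, and none are invented.
* No estimation of stillbirth counts from surveillance data; inputs are
  taken as given and validated, not modelled.
* The gestational-age-weighted stillbirth DALY proposal found in the
  literature is deliberately out of scope; the package implements only the
  decrement-times-live-births burden.
* Two-point growth comparison only; no time-series modelling.
* Group labels (MDG regions, two income tiers) are closed sets shipped as
  data and overridable via a YAML config, but no fuzzy country-name
  matching is attempted — silent mis-joins are worse than loud misses.
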