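---
title: "Dynamic activity descriptors for RFID-tracked broilers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic activity descriptors for RFID-tracked broilers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broileract)
library(data.table)
```

## The problem

Fast-growing broilers are relatively inactive, and low early-life
activity is implicated in leg weakness. Whether *increasing* early
activity would cost growth is an open question, and mean activity alone
is a blunt instrument: two birds with the same average can differ
completely in how their activity fluctuates day to day and how regular
it is within a day. `broileract` quantifies early locomotor activity of
individually RFID-tagged broilers with five *dynamic* descriptors and
relates them to average daily gain (ADG), the standard growth measure.

The measurement setting is a rectangular pen (default 1.8 m x 2.6 m)
whose floor is tiled by a 5 x 6 grid of RFID antennas. A leg-mounted
passive tag is registered roughly once per second at the antenna the
bird stands on; the antenna centre is taken as the bird's position.
Birds are weighed weekly; rounds last about five weeks, starting at age
0 or 1 day.

## From registrations to daily activity

1. **Group-level gap rule.** An interval strictly longer than 300 s in
   which *no* tag registers is sensor downtime, not behaviour, and is
   excluded exactly (the silent interval becomes an exclusion window).
   The boundary case of exactly 300 s is kept. A single silent bird
   among registering pen mates is never excluded: a stationary tag still
   registers, so individual silence is informative.
2. **Light period.** All activity quantities are computed between 07:00
   and 23:00, the main light period; birds are close to inactive in the
   dark. Handling windows (weighing, leg-band checks) are further
   excluded via configuration.
3. **Distance.** Total distance per bird-day is the sum of
   centre-to-centre distances of consecutively registered antennas.
   Pairs that straddle an exclusion window contribute nothing: movement
   during unobserved time is unknowable. Dividing by the *effective*
   recorded duration (16 h minus exclusions) gives the daily average
   distance moved per hour (DADM, m/h), comparable across days with
   different coverage. A day with zero effective seconds is missing, not
   zero.

Ages are keyed to the bird (days since hatch), not the calendar, so
rounds starting at age 0 and age 1 align. Descriptors use ages up to and
including 15 days -- the first two weeks, where individual variation in
activity is largest.

## The five descriptors

For each bird, over its non-missing days in the age window:

* **MD** -- mean of DADM (m/h).
* **Skew** -- skewness of the DADM distribution, the `b1` moment-ratio
  variant (third central moment over the cube of the (n-1)-denominator
  SD), as computed by `e1071::skewness()` with its default type.
  Requires at least 3 observed days and nonzero variance.
* **RMSE** -- each bird gets its own OLS line of DADM on age (activity
  declines roughly linearly over the first weeks); the RMSE of the
  residuals, with divisor *n* (not n-2), indexes day-to-day variability
  around the bird's own trend.
* **AC** -- lag-1 autocorrelation of those residuals, computed as the
  Pearson correlation over pairs of *consecutive ages* where both days
  were observed (a strict one-day offset; at least 3 pairs). Values near
  zero mean deviations do not persist -- fast recovery from
  perturbations.
* **ENT** -- within-day regularity. Per minute of the light period the
  bird is "active" if it registered on a different antenna than its
  previous registration; per 15-minute bin the active minutes (0-15) are
  classed 1 (0-2), 2 (3-4), 3 (5-7), 4 (8-15); the sample entropy of the
  64-class day series is averaged over complete days. Days touched by
  any exclusion are omitted entirely, because a gap deflates apparent
  activity and hence entropy.

**Sample entropy convention.** `SampEn = -ln(A/B)` where `B` counts
unordered pairs of length-`m` templates (start positions `1..N-m`)
within Chebyshev tolerance `r`, and `A` the same for length `m+1`
(positions `1..N-m-1`); self-matches excluded. Defaults `m = 2`,
`r = 0.2 x SD` of the day's class series, the conventional choices for
short series. Because the longer-template set has one member fewer, a
perfectly regular series lands on a small positive floor
`ln((N-m)/(N-m-2))` (about 0.033 at N = 64) rather than 0; the floor is
identical for every fully self-similar series, so comparisons between
birds are unaffected. The implementation is verified against
brute-force template counting on random class series.

**Outlier rule.** Within each round, a descriptor value farther than 4
SD from the round mean (mean and SD computed including the candidate)
is set to missing, cell-wise. ADG outliers are instead removed row-wise
-- the whole bird leaves the data -- before descriptors are computed.
The full filtering order is: scripted removals (sexing errors, deaths,
density removals) -> row-wise ADG outliers -> cell-wise descriptor
outliers. Note that with 4 SD and small groups a single extreme value
inflates the SD enough to mask itself; the rule only bites in
reasonably sized rounds, which matches its purpose of catching gross
recording errors in cohorts of 60-80 birds.

## Growth and statistics

ADG = (end weight - start weight) / (end age - start age), g/day,
correcting for unequal round lengths. Quartile groups pool all rounds:
`low` is ADG at or below the 25th percentile, `high` at or above the
75th (type-7 empirical quantiles; inclusive ties on both tails, with a
warning in the degenerate all-tied case).

* **Kendall tau-b** relates each descriptor to ADG on its own
  pairwise-complete set (cell-wise masking makes per-descriptor n
  differ). The tie-corrected normal approximation gives z and a
  two-sided p; a percentile bootstrap over pair resamples (B = 1000,
  seeded) gives the 95% CI.
* **Wilcoxon rank-sum** compares descriptors between the low- and
  high-ADG quartile groups.
* **Linear model.** `ADG ~ Round + StartWeight + Skew + RMSE + AC +
  ENT` with sum-to-zero round contrasts, so round effects are
  deviations from the overall mean and sum to zero over all levels. MD
  is excluded by default: it is strongly rank-correlated with RMSE
  (both reflect overall movement), and RMSE is the descriptor of
  interest. Backward elimination drops the term with the largest
  F-test p above 0.05 (factors as blocks); the survivors' two-way
  interactions are then added and elimination runs again under
  marginality (a main effect never leaves while its interaction stays).
  An AIC-based criterion is available behind a flag. The sequential
  (Type-I) ANOVA table is reported in the fitted term order, which for
  the canonical model (Round, StartWeight, RMSE) gives one F line per
  term.

When a round lacks a descriptor wholesale (e.g. entropy cannot be
computed in a round with systemic recording gaps), that round is
excluded from the model via `include_rounds`; listwise deletion would
otherwise silently do the same.

## The simulator

No real farm dataset ships with the package, so every stage is
exercised against a generative model whose parameters are the quantities
the descriptors are meant to recover:

* **Between days:** bird *j*'s target DADM on day *d* is
  `max(0, a_j + b_j d + e_d)` with stationary AR(1) deviations `e` of
  marginal SD `sigma_j` and lag-1 correlation `rho_j`. Defaults put
  cohort MD near 20 m/h with a declining trend (intercept ~26 m/h,
  slope ~-0.8 m/h/day), `sigma` ~3.9 m/h, `rho` ~0.15 -- the scale of
  real cohorts. Truncation at zero mildly skews very low-activity
  birds; it is the price of non-negative activity.
* **Within a day:** a two-state active/inactive bout process over
  minutes. Bout durations interpolate between a fixed period
  (regularity `reg = 1`) and a geometric distribution (`reg = 0`) with
  the same mean (default 5 min both states), so `reg` tunes
  within-day regularity without changing total activity; entropy
  decreases monotonically in `reg` by construction, which property
  tests confirm. The calibrated number of antenna hops,
  `round(target x 16 h / mean step)`, is spread evenly over the active
  seconds of the light period, and each hop goes to a uniformly chosen
  4-connected neighbour (`mean step` is the stationary mean hop length,
  0.397 m on the default grid). Even spacing rather than Bernoulli
  thinning keeps the daily distance within a few tenths of a percent of
  target -- at 2 m/h a day only contains ~80 hops, where independent
  thinning alone would leave ~11% relative error -- while bout
  structure and hop directions stay random. Movement runs at 5% rate
  during dark periods (a configured default, not a fitted value).
* **Registrations:** every hop second is logged plus a keep-alive
  sample every `sample_period_s` (default 1 s, the nominal recording
  rate). Because switches are always logged, reconstructed distances
  are exact at any keep-alive period; tests use 30-60 s to keep
  fixtures small.
* **Imperfections:** group-level sensor gaps (Poisson per day, uniform
  duration 330-1500 s; the first round defaults to a gap-ridden sensor
  to exercise the wholesale-entropy-exclusion path) and 30-minute
  handling windows on weigh days during which no bird registers.
* **Growth:** true ADG = `beta0 + beta_sw w0 + beta_rmse sigma_j +
  noise` (defaults 64.5, 0.41, -1.08, SD 9 g/day), linearised weights
  rounded to the scale's precision (start weight 1-2 g, later weights
  5 g). The negative `beta_rmse` couples growth weakly to activity
  variability, the relationship the statistical layer is meant to
  detect.

What the simulator does *not* emulate: body-weight feedback on
movement, density effects, diurnal trends within the light period
beyond bouts, tag loss, multi-bird antenna interference. Passing
recovery tests therefore shows the *estimators* are consistent with
their generative definitions at realistic scales -- not that real
broiler data meet those definitions.

## Numerical and design choices

* **Detrending bias.** With 15 daily observations, OLS detrending
  absorbs two degrees of freedom, so the expected RMSE is about
  `0.93 sigma` (`sqrt((n-2)/n)`), and residual autocorrelation is
  attenuated towards zero. Recovery tests target the corrected values;
  users comparing cohorts with different day counts should expect the
  same effect.
* **Minimum data:** 3 observed days for Skew and the trend fit, 3
  consecutive-age residual pairs for AC. One missing day therefore
  costs up to two AC pairs but never biases MD or Skew (missingness
  simply shrinks the sample, a property the tests assert).
* **Average marginal effects.** When the interaction stage retains a
  term like `RMSE:StartWeight`, the raw RMSE coefficient is the slope
  at start weight zero -- far outside the data. Effect-recovery checks
  therefore evaluate the *average marginal effect* (mean numerical
  derivative of the fitted surface), which coincides with the
  coefficient in interaction-free fits.
* **Problem sizes.** Property tests run at the scale where their
  expectation holds comfortably but cheaply: descriptor recovery uses
  100-300 birds x 15 days at the daily-series level (the
  antenna-to-DADM round trip is validated separately at 10% tolerance
  across targets of 2-40 m/h); model recovery uses 240 birds x 50
  seeds; type-I control 240 birds x 200 seeds; end-to-end pipeline
  checks use 2 rounds x 5 birds at a 60 s keep-alive.
* **Determinism.** All simulation randomness derives from a single
  integer seed; the same configuration reproduces byte-identical
  fixtures and run artifacts (the bootstrap is seeded from the run
  config).
* **Antenna debouncing** is deliberately absent by default: oscillating
  registrations between two adjacent antennas are genuine tag-range
  physics, and the distance definition counts them; a debounce option
  can be added upstream of `daily_distance()` without touching the
  descriptor layer.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  out_dir = "study_out",
  sim = sim_config(n_rounds = 5, birds_per_round = 24,
                   sample_period_s = 30, seed = 7),
  ent_exclude_rounds = 1,   # round 1 simulates a gap-ridden sensor
  include_rounds = 2:5,
  seed = 7)
run <- run_pipeline(cfg)
writeLines(make_report(run))
```

The report shows per-round descriptor means and SDs, the tau-b
correlation table with bootstrap CIs, the quartile-group comparison and
the selected model's coefficient table, mirroring the layout such a
study would publish.

## Known limitations

* Growth is linearised between the first and last weighing; real growth
  curves are sigmoidal, and ADG conflates early and late gain.
* The entropy class bounds (0-2/3-4/5-7/8-15 active minutes) are the
  standard quantile-derived cut-offs; `derive_class_bounds()` recomputes
  them for datasets with different activity distributions, but results
  are then not comparable across bound sets.
* The AC estimator over consecutive-age pairs is unbiased only without
  missingness patterns correlated with behaviour; heavy, structured
  missingness shrinks its effective sample quickly.
* Percentile bootstrap CIs undercover slightly for |tau| near 1; at the
  effect sizes seen in activity-growth data (|tau| < 0.2) this is
  immaterial.
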