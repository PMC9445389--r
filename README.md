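# broileract

Early-life locomotor activity of RFID-tracked broiler chickens, and its
relationship with growth.

## What it does

Fast-growing broilers are relatively inactive; low early activity is a
suspected cause of leg weakness, but the cost of *more* early activity
in terms of body-weight gain is unclear. Mean activity alone hides how
activity fluctuates, so this package computes, per bird, five **dynamic
activity descriptors** from second-resolution RFID registration logs
collected over a floor grid of antennas (default 5 × 6 antennas in a
1.8 × 2.6 m pen), over the first two weeks of life:

| Descriptor | Definition |
|---|---|
| **MD** | mean daily average distance moved per hour (DADM, m/h), light period 07:00–23:00 |
| **Skew** | skewness (b₁ variant) of the bird's daily DADM values |
| **RMSE** | √(1/n Σ(xₚ − xₒ)²) of residuals around the bird's own OLS line of DADM on age — day-to-day variability |
| **AC** | lag-1 autocorrelation of those residuals over consecutive-age pairs — persistence of deviations |
| **ENT** | mean daily sample entropy, −ln(A/B), of 64 quarter-hour activity classes (1–4) built from minute-level antenna switches — within-day regularity |

Growth is summarised as **ADG** = (end weight − start weight)/(end age −
start age) from weekly weighings. The statistical layer links
descriptors to ADG with tie-corrected Kendall **τ_b** (bootstrap 95%
CIs), Wilcoxon rank-sum comparisons of ADG quartile groups, and a linear
model `ADG ~ Round + StartWeight + RMSE + …` with **sum-to-zero round
contrasts** and two-stage backward F-test selection.

Data hygiene follows the recording reality: group-level silences > 5 min
are excluded exactly; activity is normalised by effective recorded time;
ADG outliers (> 4 SD within round) are removed row-wise, descriptor
outliers cell-wise.

Because farm RFID datasets of this kind are rarely shareable, the
package includes a **simulator** (`sim_config()`, `generate_dataset()`)
that produces registration logs, weight tables and round metadata with
the statistical structure the analysis assumes — linear activity trends
with AR(1) day-to-day deviations, bout-structured within-day movement of
controllable regularity, sensor gaps, handling windows, and growth
weakly and negatively coupled to activity variability — together with
the generating ground truth, so every stage is testable end to end.

## Worked example

```r
library(broileract)

cfg <- run_config(
  out_dir = "study_out",
  sim = sim_config(n_rounds = 5, birds_per_round = 24,
                   sample_period_s = 30, seed = 1),
  ent_exclude_rounds = 1,   # round 1 simulates a gap-ridden sensor
  include_rounds = 2:5,
  bootstrap_B = 500, seed = 1)

run <- run_pipeline(cfg)
writeLines(make_report(run))
```

Excerpt of the report this prints:

```
Per-round descriptor means (SD):
Descriptor             Overall          Round 1          Round 2      ...
Mean distance (m/h)    19.84 (5.05)     19.67 (3.51)     19.55 (5.04)
Skewness               -0.01 (0.39)     -0.09 (0.46)     0.05 (0.31)
RMSE (m/h)             3.52 (1.88)      3.75 (1.58)      3.97 (1.97)
Autocorrelation        -0.02 (0.28)     -0.01 (0.22)     -0.07 (0.33)
Entropy                0.83 (0.19)      NA               0.82 (0.14)
ADG (g/day)            78.44 (9.26)     76.96 (8.26)     78.46 (9.68)

Rank correlations with ADG (Kendall tau-b, bootstrap 95% CI):
Descriptor        tau             95% CI        z        P      n
md              0.074    [-0.048, 0.196]    1.191    0.234    120
rmse           -0.089    [-0.193, 0.016]   -1.445    0.148    120
ent             0.041    [-0.108, 0.171]    0.586    0.558     96
```

Reading it: the simulated cohort moves ~20 m/h on average in its first
two weeks, with day-to-day variability (RMSE) around 3.5 m/h; entropy is
missing for round 1, whose sensor the default scenario makes gap-ridden
(hence n = 96 for ENT). The simulator embeds a weak negative coupling
between activity variability and growth; at this 120-bird desk scale the
RMSE–ADG τ of −0.089 does not reach significance, while the
study-scale run in `scripts/acceptance.R` (320 birds) recovers it
clearly (τ ≈ −0.14, p < 0.001, model estimate ≈ −1.2 g/day per m/h).

The per-bird descriptor table is `run$descriptors`; all tables are also
written as CSV under `out_dir`, with a manifest recording the seed,
config hash and per-stage bird counts.

A thin CLI wrapper with `simulate` / `run` / `report` subcommands is
installed at `inst/cli/broileract`.

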