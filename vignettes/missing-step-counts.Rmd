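---
title: "Handling missing daily step counts in accelerometer trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing daily step counts in accelerometer trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelmi)
```

## The problem

Trials that measure physical activity with accelerometers typically ask
participants to wear the device for 7 consecutive days at each measurement
occasion (here: baseline, year 1, year 2). Missing data are endemic:
participants forget the device, remove it to bathe or swim, or batteries
fail. Because a device registers zeros both when the wearer is still and
when it is not worn, "missing" must first be *defined* before it can be
handled. accelmi implements a complete workflow for this problem: wear-time
classification, optional day-substitution, multiple imputation of daily log
step counts with interval-censored regression, delta-adjusted MNAR
sensitivity analysis, and a heteroscedastic week-average primary analysis
pooled by Rubin's rules.

## From epochs to classified days

A day's record is a stream of per-epoch step counts (5–10 s epochs).
`detect_nonwear()` flags every maximal run of zero-step epochs lasting at
least `run_minutes` (default 60) as non-wear; wear time is the worn-epoch
total. `classify_days()` then labels each day by wear time $w$:

* **missing** — $w = 0$: the device was not worn; nothing is known beyond
  the day-level covariates;
* **partial** — $0 < w < 540$ min: the recorded count is a *right-censored*
  observation: the participant took at least that many steps;
* **observed** — $w \ge 540$ min.

Both thresholds are configurable (literature alternatives use 20/40-min
runs and 6-, 8- or 10-h cut-offs). A day exactly at the cut-off counts as
observed: we read the protocol phrasing "at least 540 minutes" as
compliant; the framework's strict inequalities leave that single point
ambiguous, and the choice is visible in one place
(`classify_days()`).

## Day-substitution

When participants wear the device into the following week,
`day_substitute()` can replace a missing (or partial) in-window day with
the same weekday's record from week 2 — observed preferred over partial,
partial records keeping their censoring bound, observed in-window days
never touched. The validity of this rests on *exchangeability across
weeks given the day of the week*; the package also exposes a
sunshine-matched variant (nearest sunshine hours among week-2 days, ties
to the same weekday then the earliest day), since sunshine predicts both
wear and activity. `substitution_report()` tabulates the induced status
transitions for inspection.

## The imputation model

Imputation works on $\log(y + 1)$; the pseudo-count keeps observed
zero-step days representable, and counts are recovered as
$\max(e^v - 1, 0)$. Each cell carries an interval:

| status | interval |
|---|---|
| observed | $[\log(y{+}1),\ \log(y{+}1)]$ |
| partial | $[\log(y{+}1),\ U]$ |
| missing | $(-\infty,\ U]$ |

with $U = \log(1.5 \times \max \text{ recorded count} + 1)$, at least as
high as the log of the largest count seen in the study. The multiplier
1.5 is a modelling headroom choice: imputations may exceed any observed
day, but not implausibly so.

`chained_impute()` runs chained equations separately by arm (the
intervention may change both the level and the correlation structure of
activity). Within one cycle, each baseline day is regressed on the other
six baseline days, all fourteen year-1/year-2 days, sex, centred age and
region dummies — plus, when auxiliaries are used, baseline BMI and the
imputed day's temperature, square-root rainfall, sunshine and daylength.
The within-week mean of baseline logs then replaces the seven daily
baseline predictors when year-1 and year-2 days are imputed, reducing
noise. Each regression is a Gaussian *interval regression* (Tobit):
exact rows contribute normal densities, censored rows normal-CDF
differences; the numerical core is `survival::survreg`, the standard R
implementation of exactly this model.

Decisions the framework's description leaves open, and what we chose:

* **Initialisation** — incomplete cells start from draws of the empirical
  distribution of observed log counts for the same (group, year, weekday),
  restricted to the cell's bounds.
* **Parameter uncertainty** — each regression draws
  $(\beta, \log\sigma)$ from the asymptotic-normal approximate posterior
  at the MLE before drawing cell values from the truncated normal; the
  draw is refreshed at every cycle.
* **Visiting order** — Monday→Sunday within year, years in order 0, 1, 2;
  fixed, not randomised, for reproducibility.
* **Degeneracy** — zero-variance or near-duplicate (|r| > 0.999) predictor
  columns are dropped per-regression with a warning. If a column has
  fewer exact observations than predictors the Tobit likelihood is
  unbounded ($\sigma \to 0$); this is reported as a non-convergence error
  rather than silently regularised.
* **Small arms** — the 20+ day-predictor design needs roughly 30+
  participants per arm; below that, `pool_arms = TRUE` fits shared
  coefficients with arm indicators.
* **Reproducibility** — one seed spawns independent substreams per
  (group, imputation), so results are bit-reproducible and M could be
  parallelised without changing them.

Defaults $M = 20$ imputations and 10 cycles follow standard practice for
this design; tests and examples scale these down (to $M \in \{2,5\}$,
2–5 cycles) purely for runtime, and say so where they do.

## MNAR sensitivity: delta adjustment

If people are less active when they do not wear the device, MAR
imputation overstates their activity. The delta adjustment multiplies the
*log* step count of every originally missing/partial cell by
$\delta < 1$ after MAR imputation:
$y \mapsto \exp(\delta \log y)$, so an expected 30000 steps under MAR
becomes 17917 under $\delta = 0.95$, while 500 becomes 366.5 — larger MAR
counts shrink by more, which is the intended reading of "activity is
proportionally lower on the log scale". We apply the adjustment on the
raw log-count scale (not the internal $\log(y+1)$ scale), so these
identities are exact and adjustments compose multiplicatively; with
counts in the thousands the difference is negligible anyway. Adjusted
values may fall below a partial cell's censoring bound — deliberate: the
adjustment happens after imputation, outside the bounds.

## The primary analysis and pooling

The analysis outcome is the week average
$\bar y_{ij} = \tfrac17\sum_k y_{ijk}$ (steps/day) at years 1 and 2, with
the baseline week average as covariate. `fit_primary()` fits, by maximum
likelihood, a bivariate regression with year-2 main effect, arm
indicators, arm-by-year-2 and baseline-by-year-2 interactions, sex, age
and region fixed effects, and an *unstructured 2×2 residual covariance
per arm* — the intervention is allowed to change variability, not just
level. Estimation alternates GLS for the coefficients with closed-form
covariance updates (divisor $n_l$, i.e. ML; a df adjustment is exposed)
until the log-likelihood moves less than $10^{-8}$.

Because baseline days are imputed too, the baseline covariate varies
across imputations; each imputation is analysed separately and
`pool_rubin()` combines them: pooled estimate = mean, total variance
$T = W + (1 + 1/M)B$, degrees of freedom by the Barnard–Rubin
small-sample correction (complete-data df $= n - p$).
`arm_contrasts()` reports each intervention arm versus usual care at
years 1 and 2 (year-2 contrast = arm effect + interaction), with
delta-method variances from the pooled covariance matrices and
per-contrast Barnard–Rubin df.

## Scenarios

`run_scenario()` wires the four decisions into one reproducible pipeline;
the five presets are `plausible` (no substitution, partial as censored,
MAR, auxiliaries — the recommended primary), `suspicious` (as plausible
but $\delta = 0.95$ — the key sensitivity), `plausible_no_aux`,
`replace_days`, and `dismissive` (partial days discarded as missing,
$\delta = 0.95$). Substitution runs before bound construction so
substituted partial records keep censoring bounds. Every run emits a
manifest (flags, M, cycles, seed, version) sufficient to reproduce it
bit for bit. On a dataset with no incomplete days all five scenarios
collapse to the identical complete-data fit — a pipeline identity the
test suite asserts.

## What the synthetic generator does and does not emulate

`simulate_trial()` produces trials with known truth: 3:4:3 allocation;
participant, occasion and day-level log-normal activity (defaults:
baseline log-mean $\log 6500$, SDs 0.45 / 0.25 / 0.35 — week-average
between-person SD around 3000 steps/day, realistic for older adults at
high cardiovascular risk); a Sunday decrement (−0.15 log units); weather
generated from seasonal sinusoids at latitude 51.4 with naturally signed
correlations (sunshine with daylength and temperature, rainfall against
sunshine) and small positive/negative effects on activity; wear time for
worn days from a scaled Beta(5, 4.6) with median near 750 min; and
MCAR/MAR/MNAR non-wear with the intercept calibrated by root-finding to
the target rate. MAR missingness depends on rainfall, weekends and BMI;
MNAR additionally on the day's latent activity (negative coefficient:
under-wearing on low-activity days). Arm effects are *additive on the
count scale* (+600/+400 and +350/+250 steps/day by default), so the true
week-average contrasts versus usual care are exactly the configured
values — the estimand needs no Monte-Carlo evaluation. Partial days
record activity in proportion to worn time, making recorded partial
counts genuinely right-censored — the structural assumption the Tobit
imputation needs.

Deliberate non-realism: no within-day activity diaries (epoch streams
place steps uniformly over worn time, with non-wear as a single block);
no therapy-group clustering (dropped in the motivating analysis for
non-convergence); additive arm effects make within-arm log counts only
approximately normal at years 1–2; observed days record the full-day
count (the "missed steps only below the cut-off" discontinuity). A green
simulation test therefore establishes correctness of the machinery and
calibration under the stated world, not robustness to real-world model
misspecification.

## Numerical notes

* Truncated-normal sampling is inverse-CDF; intervals deeper than ~8 SDs
  into a tail switch to log-scale survival computations rather than
  clamping.
* The interval-regression covariance used for posterior draws is the
  observed-information covariance of $(\beta, \log\sigma)$; a minimal
  eigenvalue repair is applied before Cholesky when near-singular.
* Warm starts carry each column's previous-cycle solution into the next
  survreg call; a failed warm start falls back to a cold fit, and a
  non-converged fit is retried once with a looser tolerance before
  erroring.
* `fit_primary` requires at least 2 participants per arm and errors on
  non-positive-definite covariance updates with the arm identified.

## Known limitations

* Joint multilevel imputation (hmi/jomo-style) is out of scope; chained
  equations with interval regression is the implemented route.
* The dismissive scenario with very high missingness can make individual
  day regressions unidentified (see Degeneracy above); pooling arms or
  reducing the predictor set is then the user's call.
* Tipping-point searches over delta are a thin loop over
  `apply_delta()` left to the user.
* The delta adjustment lowers treatment contrasts *in expectation* when
  the intervention raises activity (higher arm mean ⇒ larger absolute
  shrinkage), and reliably lowers their variance; on any single dataset
  the contrast shift also carries the luck of which participants lost
  days, so the direction is not guaranteed per dataset. The test suite
  measures both.
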