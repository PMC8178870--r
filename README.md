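# accelmi

Missing-data handling for accelerometer step-count outcomes in randomized
trials.

Trials that measure physical activity with accelerometers (7-day wear at
baseline and follow-up occasions) face pervasive missing data, and the
device itself cannot distinguish "worn but still" from "not worn". This
package implements, end to end, a principled framework for that problem:

1. **Classification.** Epoch-level streams are reduced to daily records:
   runs of zero counts of ≥ 60 min (configurable) are non-wear, and a day
   with wear time *w* is **missing** (*w* = 0), **partial**
   (0 < *w* < 540 min; the count is right-censored) or **observed**
   (*w* ≥ 540 min).
2. **Day-substitution** (optional): a missing/partial in-window day is
   replaced by the same weekday's record from the following week, under
   exchangeability.
3. **Multiple imputation** of daily log counts by chained equations with
   interval-censored Gaussian (Tobit) regression, separately by arm: each
   day is regressed on the other days of its year (baseline days via their
   within-week mean for follow-up years), the other years' days, sex, age
   and region, plus auxiliary variables (baseline BMI, temperature, √rain,
   sunshine, daylength). Cell `(i,j,k)` is drawn from a normal truncated to
   `[l_ijk, u_ijk]`: degenerate for observed days, `[log y, U]` for partial
   days, `(-∞, U]` for missing days.
4. **MNAR sensitivity**: after MAR imputation, originally missing/partial
   cells are shrunk on the log scale, `y ← exp(δ log y)` with δ = 0.95
   (30000 → 17917; 500 → 366.5).
5. **Analysis and pooling**: the week average
   `ȳ_ij = (1/7) Σ_k y_ijk` at years 1 and 2 is modelled with
   treatment×year and baseline×year interactions and an unstructured 2×2
   residual covariance **per arm**; the M fits are pooled by Rubin's rules
   (`T = W + (1 + 1/M)B`, Barnard–Rubin df) and reported as arm-vs-usual-care
   contrasts.

Five named scenarios bundle the decisions: `plausible` (primary),
`suspicious` (key sensitivity, δ = 0.95), `plausible_no_aux`,
`replace_days`, `dismissive`. A synthetic trial generator with known truth
and MCAR/MAR/MNAR wear mechanisms makes every stage testable without any
real dataset.

## Worked example

```r
library(accelmi)

sim <- simulate_trial(sim_config(n_participants = 300, miss_rate = 0.2,
                                 mechanism = "MNAR", seed = 2024))
sim$dataset
#> trial_dataset: 300 participants, 7798 day records
#>   arms: 1=90 2=120 3=90
#>   day status: observed=5112 partial=1142 missing=1544
#>   auxiliaries: present

res <- run_scenario(sim$dataset, "plausible",
                    imputation_spec(M = 5, cycles = 5, seed = 1))
res
#> scenario 'plausible' (M = 5, cycles = 5, seed = 1)
#> contrasts vs usual care (steps/day):
#>  arm year estimate    se   df      lo     hi
#>    1    1   -191.7 582.0 48.8 -1361.3  977.9
#>    2    1    -64.3 602.3 23.5 -1308.9 1180.2
#>    1    2    -92.7 678.9 20.2 -1507.9 1322.6
#>    2    2    656.3 584.5 34.2  -531.2 1843.9
```

Each row is the difference in expected week-average steps/day between an
intervention arm (1 = individual therapy, 2 = group therapy) and usual
care, at year 1 and year 2, with Rubin-pooled standard errors and
Barnard–Rubin degrees of freedom. (This replicate draws 20% of days fully
non-worn under an MNAR mechanism; at n = 300 the true effects — 600/350 at
year 1, 400/250 at year 2 — sit well inside these wide intervals.
Calibration is established over replicates by the acceptance suite, not by
one draw.) The key sensitivity analysis reuses the same imputations and
shrinks formerly missing/partial cells:

```r
run_scenario(sim$dataset, "suspicious",
             imputation_spec(M = 5, cycles = 5, seed = 1))$contrasts
#>   arm year   estimate       se        df         lo        hi
#> 1   1    1 -158.95277 497.6249 147.14815 -1142.3674  824.4618
#> 2   2    1 -153.03470 483.2129  67.17039 -1117.4866  811.4172
#> 3   1    2  -37.61424 528.8290  51.60892 -1098.9787 1023.7503
#> 4   2    2  721.77768 465.6683  97.38613  -202.3987 1645.9540
```

Note the smaller standard errors under the MNAR adjustment — shrinking
imputed values towards determinism reduces between-imputation variance,
the same qualitative behaviour the framework reports on real data.

Lower-level entry points: `detect_nonwear()` / `classify_days()` /
`epochs_to_days()` (wear-time processing), `day_substitute()`,
`build_bounds()` / `chained_impute()` / `apply_delta()`,
`week_average()` / `fit_primary()` / `pool_rubin()` / `arm_contrasts()`,
and `compute_daylength()` for the photoperiod auxiliary. A thin CLI for
file-based workflows lives at `inst/cli/accelmi.R`.

See `vignettes/missing-step-counts.Rmd` for the model, its assumptions,
all numerical choices, and what the synthetic generator does and does not
emulate.
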