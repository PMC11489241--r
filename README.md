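# ataxcomp

Responsiveness-weighted composite clinical endpoints for spinocerebellar
ataxia (SCA) trials, derived from longitudinal multi-scale item data.

Individual ataxia rating-scale items (f-SARA gait/stance/sitting/speech,
FARS functional stage, CGI-I) change slowly and noisily over a 1–2 year
window, which makes disease-modification trials very large. `ataxcomp`
derives a weighted composite that is optimized for responsiveness and
carries that gain through to trial design:

1. **Standardization** — every item is mapped affinely onto [0, 1]
   (0 = best, 1 = worst); SARA items are rescaled to the f-SARA grid by a
   configurable monotone lookup.
2. **Derivation** — time from baseline is regressed on the standardized
   items by single-response partial least squares (PLS1, NIPALS, centered
   predictors, components chosen by cross-validated PRESS). Items are
   screened by Variable Importance in Projection
   (VIP_j = sqrt(p · Σ_a SS_a w²_aj / Σ_a SS_a), cutoff 0.5, with a
   clinical-override band and >5% contribution rule) and by removal of
   negative coefficients; the surviving PLS coefficients β_j are the
   composite weights, S = Σ β_j u_j.
3. **Responsiveness** — MSDR (mean/SD of change from baseline, equivalently
   the standardized response mean) for items and composite.
4. **Validation** — weight interchange across cohorts (with drop-item and
   redistribute policies for items one cohort lacks) and repeated k-fold
   resampling of MSDR bias with full re-derivation inside each fold.
5. **Treatment effects** — MMRM on composite change (arm, visit,
   arm×visit, baseline; unstructured covariance with fallbacks): LS means,
   Cohen's d, percent progression avoided
   (100·(LSM_plb − LSM_trt)/LSM_plb), and the delay in progression implied
   by the placebo trajectory.
6. **Sample size** — detectable effect d = slowing × MSDR; exact
   noncentral-t per-arm sample sizes and grids.

A longitudinal cohort simulator (`generate_natural_history()`,
`generate_trial()`) with known latent progression makes the whole pipeline
testable without access to restricted patient-level data; published summary
tables (weights, LS means, MSDRs, sample sizes) ship in `inst/extdata/` for
the arithmetic that depends only on them.

## Worked example

```r
library(ataxcomp)

# simulate a natural-history cohort, restrict to the analytic sample
cohort   <- generate_natural_history(sim_params(n_subjects = 500, seed = 11))
analytic <- filter_analytic_sample(cohort)   # 453 retained, 47 dropped

# derive the composite
model <- derive_composite(analytic)
model
#> <composite_model from 'synthetic natural history (analytic)': 4 items, 2 PLS component(s)>
#>           item  weight    vip pct_contribution
#> 1   fsara_gait  1.8913 0.8663             2.85
#> 2 fsara_stance  0.8320 0.8269             1.26
#> 3    fars_func  5.7920 0.7268             8.74
#> 4          cgi 57.7318 1.4274            87.15
#> removed: fsara_speech ( negative_coefficient ), fsara_sitting ( vip_below_threshold )
```

CGI dominates because it rates change directly; the two excluded items are
logged with their reasons. The composite beats every single item on
responsiveness:

```r
responsiveness_report(analytic, model)
#>        measure   msdr   n
#> 1   fsara_gait 1.3148 453
#> 2 fsara_stance 1.1607 453
#> 3    fars_func 1.3777 453
#> 4          cgi 1.9540 453
#> 5    composite 2.0562 453
```

Apply the model to a simulated 48-week trial in which treatment halves the
progression rate:

```r
trial <- generate_trial(trial_params(n_per_arm = 100, slowing_fraction = 0.5,
                                     seed = 42))
estimate_effects(trial, model)
#> final-visit difference 4.1282 (SE 0.7519, 95% CI 2.6546 to 5.6018, p = 4e-08)
#> Cohen's d 0.800; progression avoided 60.8%; delay 7.3 months
```

The true slowing is 50%; this 100-per-arm replicate estimates 60.8%
progression avoided. Sample sizes from published responsiveness values (a
composite MSDR of 0.8276 vs 0.4826 for f-SARA) show the payoff — roughly a
third of the patients for the same power:

```r
power_table(c(fsara = 0.4826, composite = 0.8276))
#>    endpoint   msdr power slowing effect_size n_per_arm
#> 1 composite 0.8276   0.8     0.3      0.2483       256
#> 2 composite 0.8276   0.8     0.5      0.4138        93
#> 3 composite 0.8276   0.9     0.3      0.2483       342
#> 4 composite 0.8276   0.9     0.5      0.4138       124
#> 5     fsara 0.4826   0.8     0.3      0.1448       750
#> 6     fsara 0.4826   0.8     0.5      0.2413       271
#> 7     fsara 0.4826   0.9     0.3      0.1448      1004
#> 8     fsara 0.4826   0.9     0.5      0.2413       362
```

A thin command-line front end (`inst/cli/ataxcomp`) exposes the same
pipeline as `simulate`, `derive`, `score`, `msdr`, `validate`, `effects`
and `power` subcommands.

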