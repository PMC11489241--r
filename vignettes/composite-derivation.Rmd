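---
title: "Deriving responsiveness-weighted composite endpoints for ataxia trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving responsiveness-weighted composite endpoints for ataxia trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataxcomp)
```

## The problem

Spinocerebellar ataxias (SCAs) are slowly progressive neurodegenerative
diseases. Trials of disease-modifying treatment must detect a difference in
*rate of decline* within a year or two, but the individual items of the
standard clinical scales — the four f-SARA items (gait, stance, sitting,
speech; 0–4 each), the FARS functional stage (0–6) and the clinician's global
impression of change (CGI-I, 1–7) — each move slowly and noisily over such a
window. A composite that weights items by how reliably they track progression
can be several times more responsive than any single scale, which translates
quadratically into smaller trial sample sizes.

`ataxcomp` implements the full workflow: item standardization, derivation of
the composite weights by single-response partial least squares (PLS1)
regression with Variable-Importance-in-Projection (VIP) screening, validation
of the weights by cohort interchange and repeated k-fold resampling,
treatment-effect estimation on the composite in a two-arm trial, and
sample-size planning from the composite's responsiveness. Because the
patient-level natural-history and trial datasets this methodology was
developed on are access-restricted, the package also ships a longitudinal
cohort simulator with known ground truth, so every stage of the pipeline can
be exercised and checked end to end.

## Score standardization

Each raw item score is mapped affinely onto $[0,1]$ with 0 the best and 1 the
worst possible state (`standardize_item()`), regardless of the item's native
direction. Because all items then share one range, the PLS regression is run
on *centered but not variance-scaled* predictors: the raw coefficients are
directly comparable across items and their normalized values are the percent
contributions reported for the composite. Autoscaling would silently change
that arithmetic, which is why it is off by default and exposed nowhere.

SARA items from natural-history cohorts are first carried onto the 5-point
f-SARA grid by a per-item monotone lookup table. The shipped default is
proportional rounding, `round(raw * 4 / sara_max)` with halves rounded up;
the table is configuration-driven (`scale_config()`) so a study-specific
mapping can be substituted. CGI-I rates *change* and has no observed baseline
value; the baseline is imputed as the "no change" midpoint (raw 4, unit 0.5),
configurable via `cgi_baseline_value`.

## The derivation model

Disease progression is treated as approximately linear over the observation
window — the analytic-sample filter (`filter_analytic_sample()`) restricts to
ambulatory patients (baseline gait within a 1–7 raw-score window) with
complete item data at baseline and at 12 or 24 months, i.e. patients in the
linear phase of an overall sigmoidal decline. Time from baseline is then the
*response* and the standardized items are the predictors:

$$t_{iv} = \beta_0 + \sum_j \beta_j\, u_{ijv} + \varepsilon_{iv},$$

fit by NIPALS PLS1 (`fit_pls1()`) over all pooled subject-visits. PLS, unlike
OLS, remains stable under the strong collinearity of ataxia items and
balances predictor variance against response variance. The number of latent
components is chosen by cross-validated PRESS (`select_components()`):
leave-one-out up to 200 rows, 20 deterministic interleaved folds beyond that,
taking the smallest number of components within 5% of the minimum PRESS (a
parsimony rule; with highly informative predictors the second component can
genuinely pay for itself, so the count is data-driven rather than fixed).

Item selection then runs as a loop (`derive_composite()`):

1. fit PLS1 on the current candidate set;
2. while any coefficient is non-positive, remove the most negative item and
   refit (logged as `negative_coefficient`; ties broken by candidate order);
3. compute VIP scores,
   $\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a SS_a}$ with
   $SS_a = q_a^2 \mathbf{t}_a'\mathbf{t}_a$, which satisfy
   $\sum_j \mathrm{VIP}_j^2 = p$;
4. remove items with VIP at or below the Wold-type cutoff (0.5), *unless* the
   item is flagged clinically essential, its VIP is at least `vip_near`
   (default 0.45, operationalizing "approximately at the cutoff") and it
   contributes more than 5% of the total weight;
5. repeat until stable.

The final coefficients are the composite weights; the composite score of a
visit is $S = \sum_j \beta_j u_j$, ranging from 0 to $\sum_j \beta_j$, and a
visit missing any retained item is not scored (complete-case per visit).
Every excluded candidate appears in the removal log with its reason, so the
derivation is fully auditable.

## Responsiveness: the MSDR

Responsiveness is summarized by the mean-to-standard-deviation ratio of
change from baseline (`msdr()`), identical in form to the standardized
response mean: $\mathrm{MSDR} = \bar{\Delta} / s_\Delta$ with the sample
($n-1$) standard deviation. The follow-up value defaults to the last
available of the configured visits (12/24 months for natural history, week
48 for trials), matching the analytic-sample definition; a fixed-visit rule
is available. The MSDR is invariant to positive rescaling of the measure, so
the composite's MSDR does not depend on the overall scale of its weights —
only on their ratios.

## Validation

Two checks probe whether derived weights generalize:

* **Weight interchange** (`interchange_weights()`): score cohort B with the
  weights derived on cohort A and compare MSDRs. When the foreign model
  contains an item the target cohort never measured, that weight is dropped;
  when the cohort measures an item the foreign model lacks, the item can be
  inserted at a stated share c with weight $W c/(1-c)$
  (`redistribute_weights()`), which leaves the pre-existing proportions
  untouched and gives the new item exactly share c.
* **Repeated k-fold resampling** (`kfold_bias()`): subjects (never individual
  visits) are partitioned into k folds; the *entire* derivation — component
  selection and item screening included — is re-run on each training set and
  its MSDR evaluated on the held-out fold. Default 5 folds × 40 repartitions
  = 200 estimates. Percent bias is signed test-relative-to-train
  ($100(\mathrm{MSDR}_{test}-\mathrm{MSDR}_{train})/\mathrm{MSDR}_{train}$),
  so negative values mean out-of-sample degradation. Re-running the full
  selection inside each fold is the stricter, honest form of this check.

## Treatment effects

`estimate_effects()` fits the standard MMRM to the composite change from
baseline at post-baseline visits: fixed effects for arm, visit, arm × visit
and the baseline composite; within-subject covariance unstructured with
per-visit variances, falling back to compound symmetry and finally
independence when estimation fails (degenerate or tiny samples). The
covariate list follows standard MMRM practice; inference for the final-visit
least-squares-mean difference uses a normal approximation (documented
simplification — with hundreds of subjects the refinement from explicit
small-sample degrees of freedom is negligible). From the LS means it derives:

* **percent progression avoided**, $100(\mathrm{LSM}_{plb} -
  \mathrm{LSM}_{trt})/\mathrm{LSM}_{plb}$ at the final visit;
* **Cohen's d**, the LSM difference standardized by the pooled observed SD
  of final-visit change across arms (the denominator definition is a
  documented choice — no standard exists for MMRM-based d);
* **delay in progression**: the follow-up duration minus the earliest time
  at which the piecewise-linear placebo LSM trajectory reaches the treated
  arm's final change.

## Sample size

A treatment that slows progression by a fraction $s$ shrinks the mean change
by $s\bar\Delta$ while leaving the SD essentially unchanged, so the
detectable standardized effect is $d = s \cdot \mathrm{MSDR}$.
`sample_size_per_arm()` returns the smallest per-arm n (1:1 allocation)
whose exact two-sided noncentral-t power (ncp $= d\sqrt{n/2}$, df $= 2n-2$)
meets the target; `power_table()` tabulates the grid over endpoints,
slowings and power targets. Per-arm (rather than total) n is the convention
here; the published endpoint-comparison grid shipped in
`reference_sample_sizes()` is reproduced cell for cell under exactly this
convention, which resolves the ambiguity empirically.

## The synthetic cohort generator

`generate_natural_history()` and `generate_trial()` simulate the latent
model

$$z_i(t) = z_{i0} + r_i t, \qquad r_i \sim N(r_{g(i)}, \sigma_r),$$

with genotype-specific mean rates, and observe it through per-item logistic
links $u_{ij}(t) = \mathrm{logit}^{-1}(b_j + \lambda_j z_i(t) +
\varepsilon_{ijt})$ discretized to the item's ordinal grid. CGI-I instead
rates the *change* $z_i(t) - z_i(0)$, mapped monotonically onto 1–7 around
the no-change midpoint. Treated arms progress at $(1-s) r_i$; visits follow
the natural-history (0/12/24 months) or trial (weeks 0/8/24/48, converted at
12/52 months per week) schedule; dropout is missing-completely-at-random per
visit. Each generator call consumes one explicitly seeded stream and
restores the caller's RNG state, so output is byte-reproducible.

Parameter defaults and rationale:

* genotype mix mirrors a US natural-history cohort (SCA3 largest at 36%);
* item intercepts $b_j$ reproduce typical ambulatory baseline severities
  (gait ≈ 1.5/4, sitting lowest);
* sensitivity-to-noise ratios are well separated across items (sitting least
  responsive, CGI most) — the ordering the derivation must recover;
* rates (0.026–0.055 latent units/month), between-subject rate SD (0.010)
  and measurement noise (SD 0.25–0.40) are chosen so that a 200-per-arm,
  48-week trial estimates percent progression avoided with a standard error
  of a few points. This places the synthetic composite's natural-history
  MSDR (≈ 1.3–2.0 at item/composite level) at — and deliberately above — the
  upper end of published ataxia values: the simulator's job is parameter
  recovery with usable precision, not distributional mimicry of any one
  cohort.

What the generator does *not* emulate: the sigmoidal whole-disease course
(only its locally linear phase), genotype-specific item *profiles* (genotypes
differ only in rate), informative dropout, rater effects, and floor/ceiling
clustering beyond what the logistic link and ordinal grids induce. Passing
recovery tests on these cohorts therefore demonstrates the correctness of
the estimation machinery under the stated model, not the clinical validity
of any particular weight set on real patients.

## Numerical choices and degenerate inputs

* Constant predictor columns get weight 0 with a warning; rank exhaustion
  reduces the component count with a warning; a response uncorrelated with
  every predictor is an error.
* Removal ties (equal negative coefficients) resolve by candidate order;
  `derive_composite()` is idempotent on its own retained set and invariant
  to candidate ordering.
* MSDR requires n ≥ 2 and positive change variance; zero-variance change is
  an explicit error, as is a non-positive placebo LSM for percent avoided.
* A zero-variance baseline covariate is dropped from the MMRM (it carries no
  information and would make the design singular); a fully deterministic
  trial then yields exact LS means with zero SE via the OLS fallback.
* Percent contributions require strictly positive weights and sum to 100
  within 0.01.
* Trial weeks convert to months at 12/52 exactly (week 48 ≈ 11.077 months);
  visit matching uses the stored numeric values, never re-parsed labels.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: derivation cohorts of
250–1000 subjects; 20-seed replicate experiments for ranking recovery and
composite-versus-item responsiveness; 3 replicate trials at 200/arm
(slowing 0.5) and 50 trials at 100/arm (slowing 0.75) for effect recovery;
5-fold × 40 repartitions for resampling bias; and 100,000 Monte-Carlo
replicates for the noncentral-t power check. These sizes make the stochastic
checks decisive (binomial or CLT margins of at least ~3 SD) while keeping a
full run to a few minutes.

## Known limitations

* The shipped SARA→f-SARA table is a proportional stand-in; substitute the
  study-specific mapping where available.
* Whether baseline CGI should enter the PLS fit (imputed) or only follow-up
  CGI values is not settled; the imputed-midpoint default keeps baselines
  scoreable and is configurable.
* The MMRM uses a normal approximation for inference and offers no
  multiple-imputation handling of dropout.
* Published weight/VIP/MSDR *values* from restricted cohorts cannot be
  reproduced computationally; the package reproduces all arithmetic that
  depends only on published summaries and validates everything else by
  parameter recovery on synthetic data.
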