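---
title: "Methods: daily affect, mobility and early adolescent alcohol use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily affect, mobility and early adolescent alcohol use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emaroam)
```

## The scientific problem

Early adolescent alcohol use is rare, episodic, and strongly shaped by the
situations of daily life. The design this package implements samples that
daily life directly: adolescents carry a study phone for 14 days, answer six
fixed-time ecological momentary assessment (EMA) prompts per day (09:00,
11:00, 14:00, 16:00, 18:00, 20:00) about momentary affect, craving,
rumination and social context, and report each morning whether they drank
alcohol the previous day, while the phone records their GPS position about
once a minute. The analysis asks which day-level experiences and mobility
patterns co-occur with drinking days.

The package covers the full path from raw inputs to inference:

1. **Geospatial**: per-day roaming entropy and trigger-point contact counts
   from raw GPS fixes.
2. **EMA**: prompt scoring, daily aggregation, the day-shifted alcohol
   outcome, compliance and prompt-count filters.
3. **Modelling**: a binomial random-intercept multilevel model with
   deviance-based model comparison, Nakagawa pseudo-R², and a
   prompt-threshold sensitivity series.
4. **Synthetic data**: a calibrated generator that emulates all four raw
   inputs, so every stage — including parameter recovery of the published
   coefficients — runs without access to any real participant data.

## Geospatial measures

### Roaming entropy

A "place" is a latitude-longitude pair rounded to the fourth decimal, a
cell of roughly 11 m — about a small house or street section. For one
participant-day with $T$ recorded fixes falling into $n$ unique cells with
relative frequencies $p_i$, roaming entropy is

$$\mathrm{RE} = \frac{-\sum_{i=1}^{n} p_i \ln p_i}{\ln T}.$$

RE is 0 when the participant never left one cell and 1 when every recorded
fix fell in a distinct cell. Two numerical choices deserve emphasis:

* **Normalizing constant.** $\ln T$ (the day's fix count) is used because it
  is the unique normalizer under which "every place visited was unique"
  equals exactly 1. The base of the inner logarithm is immaterial: any base
  cancels under this normalization (natural logs are used throughout).
* **Rounding.** Cell assignment rounds half-away-from-zero on the decimal
  representation (49.48735 becomes 49.4874), not the IEEE half-even rule of
  `round()`. A small inner rounding step strips binary floating-point fuzz
  before the tie test. Rounding operates on WGS84 degrees, not projected
  metres.

Days are bounded at local civil midnight in a configurable timezone
(default `Europe/Berlin`); fixes are assigned to days before any
computation. Duplicate timestamps keep the first fix; GPS gaps are not
imputed — frequencies are over recorded fixes only, which is what a
"relative within-day frequency" means. A single-fix or single-cell day has
RE defined as 0, and the result is clamped to $[0,1]$ against
floating-point overshoot.

### Trigger-point contacts

Places where alcohol may be especially salient are categorized into five
closed classes: nightlife, culture, leisure, peers, and meeting spots.
Contact is defined purely by closeness: a fix is "in contact" with a
category when it lies within 15 m (great-circle, sphere radius 6,371,000 m)
of at least one point of interest (POI) of that category. A *contact
episode* is a maximal run of consecutive in-contact fixes — hours parked at
one bar count once; leaving the radius for at least one fix and returning
starts a new episode. A fix within 15 m of POIs of several categories
counts in each. Episodes are defined on the raw fix sequence with no
minimum dwell and no hysteresis, because the underlying definition is
closeness alone; the 15 m radius is configurable, and counts are insensitive
to small radius changes whenever geometry keeps paths clearly inside or
outside (the package's tests check 14 m vs 16 m).

## EMA pipeline

Per prompt, positive and negative affect are means of 5 items each (1-7
scale); craving (6 items) and rumination (4 items) are anchored
1 = "totally agree" to 7 = "totally disagree" and reverse-coded as $8-x$
before averaging, so higher always means more of the construct. The single
social-context item ("Are you currently alone?") maps to 1/0.

Per participant-day, construct scores are means over answered prompts.
Social context is implemented as the *proportion* of answered prompts alone
rather than a raw sum: a proportion is the only reading consistent with
sample descriptives in the 0-0.55 range on a 0-6 count support, and it is
invariant to how many prompts were answered. A raw-sum variant is available
(`aggregate_days(..., social = "sum")`).

The alcohol outcome is the morning report "Did you drink alcohol
yesterday?", assigned to the previous calendar day; a missed 09:00 prompt
leaves the previous day's outcome missing. The protocol schedules no
morning prompt after the last study day, so the final day's outcome is
structurally missing in observed data. Weekend days are Friday, Saturday
and Sunday. Participants with fewer than half of the 84 scheduled prompts
answered are excluded; modelled days additionally require at least `k`
answered prompts (default 4), an observed outcome, and complete geospatial
summaries.

## The multilevel model

For day $d$ of participant $j$,

$$\operatorname{logit} P(y_{dj}=1) = \beta_0 + \mathbf{x}_{dj}^\top
\boldsymbol\beta + u_j, \qquad u_j \sim N(0, \sigma_u^2),$$

with 14 fixed effects (five EMA constructs, weekend, roaming entropy, five
trigger-point counts, age group, sex) and a participant random intercept.
Estimation is maximum likelihood with the Laplace approximation
(`lme4::glmer` with the `nloptwrap` BOBYQA optimizer; adaptive quadrature
available via `nAGQ`). Predictors enter on their raw scales — the published
roaming-entropy coefficient's magnitude relative to its $[0,1]$ support is
only consistent with unstandardized entry. Age is coded 0 = 14-year-olds,
1 = 16-year-olds; sex 0 = male, 1 = female; weekend 0/1.

The overall model test compares the deviance of the full model with a null
model holding only the intercept and the random intercept, refitted on the
identical rows; the statistic is chi-square with 14 df (the number of fixed
terms removed). The random intercept itself is tested against an ordinary
logistic fit with a boundary-corrected likelihood-ratio test (50:50 mixture
of $\chi^2_0$ and $\chi^2_1$); a Wald test on a variance component at its
boundary is unreliable, so only the LRT route is provided.

Variance explained is reported as the Nakagawa-Schielzeth pair with the
logistic distribution-specific variance $\pi^2/3$:

$$R^2_m = \frac{\sigma_f^2}{\sigma_f^2+\sigma_u^2+\pi^2/3}, \qquad
R^2_c = \frac{\sigma_f^2+\sigma_u^2}{\sigma_f^2+\sigma_u^2+\pi^2/3},$$

where $\sigma_f^2$ is the variance of the fitted fixed-effect linear
predictor over the estimation rows. No multiple-testing correction is
applied; inference is two-sided at $\alpha = .05$.

A sensitivity series refits the model at every prompt-count threshold
$k = 1,\dots,6$; retained-day counts are non-increasing in $k$ by
construction, and an unfittable threshold is marked failed without
aborting the series.

## The synthetic-data generator

The generator's defaults *are* the study conditions: 52 participants (24
aged 14; 26 female; sex crossed within age group 12/12 and 14/14; 15
assessed before pandemic restrictions), 14 days starting on a Monday (so
the window holds 6 weekend days), 6 prompts/day answered independently with
probability 0.797 (the sample's mean compliance), per-minute GPS, and the
published coefficient vector as the generating $\boldsymbol\beta$.

### Calibration choices

* **Random-intercept SD.** The study did not report $\sigma_u$ or an ICC.
  Inverting the Nakagawa equations with the published pair
  $(R^2_m, R^2_c) = (0.244, 0.405)$ gives a total latent variance
  $(\pi^2/3)/(1-R^2_c) = 5.529$, hence $\sigma_f^2 = 1.349$,
  $\sigma_u^2 = 0.890$, $\sigma_u = 0.944$
  (`derive_variance_components()`). This is an inference from printed
  quantities, not a printed value.
* **Covariates.** Daily constructs are generated as participant-level mean
  plus day-level Gaussian noise with the total SD split 50/50 between
  levels (only total SDs were published), clamped to legal ranges; weekend
  comes from the real calendar; trigger-point counts are Poisson with rates
  chosen once as plausible daily contact frequencies (0.3, 0.5, 0.8, 1.0,
  0.5 for culture, nightlife, leisure, meeting spots, peers). Covariates
  are generated independently; no cross-correlations were published.
* **Roaming-entropy spread.** No RE descriptives were published. Its mean
  is set to 0.20 — a plausible low daily-mobility level for adolescents in
  a compact urban area — and its SD is *derived* at configuration time by
  solving $\sum_k \beta_k^2 \operatorname{var}(x_k) = \sigma_f^2 = 1.349$
  for the single free variance (`derive_re_sd()`, giving SD ≈ 0.070). The
  generator is thereby exactly calibrated to the published variance
  decomposition.
* **Centered linear predictor.** Outcomes are drawn from
  $\eta = \beta_0 + (\mathbf{x}-\boldsymbol\mu)^\top\boldsymbol\beta + u_j$:
  the published intercept is interpreted as the log-odds of drinking at
  covariate means for an average participant. With raw (uncentered) entry,
  $\boldsymbol\beta^\top E[\mathbf{x}] \approx 6.3$ would put the daily
  drinking probability near 0.9 — irreconcilable with the published
  average of 1.1 drinking days per participant over 14 days. Centering
  reproduces that observed frequency (about 0.8-1.1 drinking days per
  participant) while leaving every slope, and both pseudo-R² components,
  unchanged; fitted (raw-scale) intercepts are simply shifted by
  $-\boldsymbol\mu^\top\boldsymbol\beta$.
* **Missingness** is independent Bernoulli per prompt (only mean compliance
  was published). A drinking-dependent nonresponse mechanism is out of
  scope.

### Geography

Synthetic trajectories live on a flat grid of exact 4-decimal coordinates
around a configurable origin (default 49.49 N, 8.47 E, so the rounding rule
behaves as in the study region), with 1e-3-degree spacing (~110 m) keeping
distinct anchors far outside one another's 15 m contact radius. Three
profiles exist: *stationary* (one anchor all day, RE = 0), *roamer* (every
fix a fresh cell, RE = 1), and *commuter* (consecutive dwell blocks over
$k$ anchors with configurable dwell fractions). Full-study simulation
draws a target RE per day from the configured distribution and picks
$k \approx T^{\mathrm{RE}}$ equal-dwell anchors, whose realized entropy
$\ln k/\ln T$ is recorded as truth — so the module-recomputed entropy can
be checked against the generator's plan to 1e-9. POIs are placed either
exactly on grid points (contact distance 0) or offset ~33 m (safely outside
the radius), which also underpins the radius-robustness tests. By default
the number of near POIs per category is calibrated so the expected daily
contact count under the trajectory model matches that category's
configured Poisson rate; realized geometry-path contacts are nevertheless
at most one per dwell block, hence less dispersed than the Poisson counts
the direct recovery path draws.

The generator emulates the *statistical structure* of the study inputs —
compositions, moments, missingness rate, the outcome law — not human
mobility realism: no roads, no Lévy flights, no diurnal rhythm, no
accuracy noise, and item responses are exchangeable given the daily latent
construct. Passing recovery tests therefore demonstrates that the pipeline
and estimator are faithful, not that the published findings would replicate
in new data.

### AUDIT

Participant AUDIT items (10 items, 0-4, summed to 0-40) are generated with
a level that increases with the participant's random intercept, so general
alcohol involvement correlates positively with generated daily drinking, as
observed in the study; the strength of that correlation was not calibrated
to a published value.

## Problem sizes and runtime choices

Parameter recovery uses 200 replicate datasets of the full study size
(52 × 14 = 728 participant-days) fitted with Laplace approximation;
null-calibration of the 14-df likelihood-ratio test uses 500 replicates
with all fixed effects zero (event rate one half, so every replicate is
comfortably estimable). The optimizer skips post-hoc derivative
diagnostics (`calc.derivs = FALSE`) for speed; a convergence flag and
captured optimizer messages are kept on every fit object. Pipeline
mechanics are tested on reduced geometries (tens of participants, tens of
fixes per day) because the computations are scale-free; the generator's
defaults always remain the study-scale conditions.

## Known limitations

* Fitted pseudo-R² components at this sample size are noticeably
  upward-biased relative to their generating values, because
  $\operatorname{var}(X\hat\beta)$ inherits the sampling error of 15
  estimated coefficients from only ~50 drinking events; the recovery
  harness reports the mean fitted values as they are.
* Person-level coefficients (age, sex) are weakly identified with 52
  participants and a rare outcome; individual replicates can yield large
  estimates even though day-level coefficients recover well.
* The EMA item layer rounds and clamps responses to the 1-7 grid, which
  slightly biases scored daily means upward for constructs whose latent
  mean sits near the scale floor (negative affect, craving); published
  descriptives for negative affect (0.89 in one subgroup) in fact fall
  below the nominal scale minimum, suggesting an unreported rescaling in
  the source — the generator calibrates the latent day-level values, which
  is also what the recovery harness consumes.
* Real movisensXS exports, the full 43-item battery, map matching and
  stay-point clustering are out of scope.
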