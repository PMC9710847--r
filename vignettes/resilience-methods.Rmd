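---
title: "Methods: classifying academic resilience and modelling its correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying academic resilience and modelling its correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`resilgap` operationalizes a simple idea: a child who entered school
developmentally vulnerable is *academically resilient* if, by Grade 3,
they achieve at least as well as their school-entry stratum would
predict. This vignette documents the model, the conventions and
numerical choices behind the implementation, what the bundled synthetic
cohort does and does not emulate, and the package's known limitations.

## Stratification

School-entry scores are cut at the 10th, 25th and 50th percentiles into
four groups (`V10`, `V10_25`, `V25_50`, `TOP50`). Two conventions are
fixed throughout:

* **At-or-below assignment.** A child exactly at a cutpoint belongs to
  the lower group, so "vulnerable" means *at or below* the 50th
  percentile.
* **Type-7 empirical quantiles** (R's default interpolating definition)
  when cutpoints are computed from the sample itself.

Whether stratification should use sample-internal percentiles or
external population norms is genuinely open: census-style developmental
instruments publish national percentile bands, and an analytic sample
that is positively selected (e.g. higher socio-economic position than
the excluded families) will then have fewer than 50% of children below
the national median. Both are supported: `assign_percentile_groups()`
defaults to sample percentiles and accepts explicit cutpoints;
`norm_referenced_cutpoints(vulnerable_share)` produces thresholds for a
standard-normal entry score that hit a chosen vulnerable share while
preserving the population 10:15:25 ratio between the vulnerable strata.
The analysis drivers use `vulnerable_share = 0.3687`, a typical value
for a positively selected cohort scored against national norms, giving
roughly 780 vulnerable children in a sample of 2118.

## Predicted scores and the resilience rule

For each achievement domain, ordinary least squares regresses the score
on three stratum indicators with `TOP50` as reference. Writing $b_s$ for
the raw coefficient of stratum $s$, $M$ for the TOP50 sample mean and
$\mathrm{SD}$ for the full-sample standard deviation of the outcome, the
stratum's predicted score is

$$P_s = M - |\beta_s|\,\mathrm{SD}, \qquad \beta_s = b_s / \mathrm{SD}.$$

Three conventions deserve note:

* **Standardization is with respect to the outcome only**
  ($\beta = b/\mathrm{SD}_y$); the stratum indicators are left raw.
  $\mathrm{SD}$ is the sample standard deviation of achievement over the
  full analytic sample — not a standard error, which would shrink $P$
  toward $M$ by $1/\sqrt{n}$ and collapse the stratum separation.
* **Sign convention.** The package stores $\beta_s$ signed (negative
  when a stratum sits below the reference) and computes
  $P_s = M + \beta_s\,\mathrm{SD} = M + b_s$; the formula above, which
  states the deficit as a magnitude, is the same quantity. The decisive
  consistency requirement is that in the covariate-free fit $P_s$ equals
  the stratum's own sample mean *exactly* — the test suite asserts this
  identity at $10^{-9}$ and uses "actual ≥ own-stratum mean" as an
  independent classification oracle.
* **Ties are resilient.** A child whose actual score exactly equals the
  predicted score is classified resilient (in continuous data ties have
  probability zero; the boundary rule still must be fixed).

`fit_baseline_regression()` accepts an optional covariate list for
sensitivity analysis; the default is stratum-only, the minimal model
that yields one shared predicted score per stratum. Classification is
restricted to vulnerable children; `TOP50` children are
"not applicable", never "resilient", and vulnerable children missing an
achievement score are excluded with a warning and a reported count
rather than silently dropped.

A useful consequence of the stratum-only default: predicted scores are
equivariant under affine rescaling of achievement ($y \mapsto ay + c$,
$a > 0$ maps $P \mapsto aP + c$), so resilience labels are invariant to
the scale and origin of the test score. This is tested directly.

## Group comparison conventions

* **Pearson chi-square without continuity correction.** The uncorrected
  statistic is what reproduces printed two-by-two comparisons in this
  literature; Yates' correction does not. Expected counts below 1
  produce a warning but not a failure; a zero margin is an error.
* **Classical (equal-variance) one-way ANOVA**, computed by the
  standard between/within decomposition. In the fully degenerate case
  (no between-group variability at all) $F$ is reported as 0 with
  $p = 1$ rather than 0/0.
* **Bonferroni family = the three pairwise contrasts within one
  domain** (ongoing vs resilient vs strong-in-Prep): each pooled-variance
  t p-value is multiplied by 3 and capped at 1. The explanatory screen
  is reported *unadjusted* at α = .05 and .01 — it is a screening step,
  not confirmatory inference.
* **Complete-case per variable** in the screens, which precede the
  imputation-based final model.
* **Benchmark flags use at-or-above**: a group mean exactly at the
  published grade-level equivalent counts as meeting it. Benchmarks are
  configuration (score points per domain), not data.

## The synthetic cohort

The generator exists so that every pipeline stage is testable without
access-restricted cohort data. Its defaults are fixed study conditions,
not tuning knobs.

**Structure.** A single latent multivariate-normal draw covers entry
ability plus 34 covariates; the correlation matrix comes from a
six-factor loading structure (general ability, child regulation,
parenting quality, school/teacher context, socio-economic position,
sleep), which guarantees positive definiteness and gives plausible
cross-correlations (e.g. attentional regulation loads on both ability
and regulation; parenting consistency and anger share a parenting
factor; earlier-wave auxiliaries load on the same factors as their
later counterparts). Binary covariates arise by thresholding the latent
normal at the target prevalence, ordinal ones by quantile cuts, so one
correlation engine serves all measurement types.

**Achievement.** For each domain,
`score = intercept + stratum offset + Σ (effect per latent SD) + N(0, σ)`,
clamped to [0, 1000]. Defaults: stratum offsets (−80, −55, −30) points
for reading and (−75, −52, −28) for numeracy; residual σ = 60 points;
TOP50 anchor means 480 (reading) and 455 (numeracy) — the intercept is
solved in closed form for the covariate drift induced by conditioning
on above-median ability. Covariate effects (score points per latent
covariate SD): attentional regulation (20, 22), receptive vocabulary
(15, 13), socio-economic position (13, 12), sleep problems (0, −9) and
female gender (0, −10), all others zero. This calibration was chosen
once, analytically, so that on the latent-response scale the
attentional-regulation and vocabulary effects dominate (standardized
magnitudes roughly 0.2–0.3 at study scale) while sleep problems and
gender matter for numeracy only — the qualitative pattern the path
model should recover — with bivariate differences in other variables
(parenting consistency and anger, peer problems) arising purely through
the correlation structure, not through direct effects.

**Missingness.** Each target variable's missingness indicator follows a
logistic model in standardized fully-observed drivers (defaults:
socio-economic position with slope −0.5 per SD, gender +0.25), with the
intercept solved by root-finding so the realized rate matches the
target. Default rates: 18–24% on teacher-questionnaire variables
(teacher self-efficacy at the 24% ceiling), ~2–5% on child-report and
administrative linkage variables, zero on parent-reported variables.
Entry scores and achievement are never masked. Because missingness
depends only on observed drivers, the mechanism is missing-at-random by
construction; a Kolmogorov–Smirnov check within driver strata confirms
it in the test suite.

**What the generator does not emulate** — and hence what passing tests
cannot show about real data: entry scores are a symmetric normal latent,
whereas real teacher-rated domain scores are bounded and skewed with
heavy ties; achievement noise is homoscedastic across strata; there is
no school-level clustering, no survey design weights, no item-level
instrument structure, and no not-missing-at-random mechanism. Results on
synthetic data validate the *machinery*, not the substantive findings.

## Multiple imputation and pooling

Chained equations, hand-rolled with deliberately standard components:

* **Predictive mean matching** for continuous and ordinal variables:
  a Bayesian draw of the regression parameters (σ² from the scaled
  inverse-χ², coefficients from their normal posterior), type-1
  matching (observed predictions from the posterior mode, missing
  predictions from the draw), k = 5 nearest donors, one donor sampled
  uniformly. PMM only ever imputes observed values, so ordinal scales
  and bounded supports are respected automatically.
* **Bayesian logistic draws** for binary variables.
* Variables are visited in order of increasing missingness; all other
  model variables — including the earlier-wave auxiliaries — serve as
  predictors; observed cells are never modified (asserted bitwise in
  tests).
* Defaults: m = 40 datasets, 20 sweeps. The trace (per-sweep mean/SD of
  the imputed values) is kept, and a crude drift heuristic warns on
  apparent non-convergence; no formal diagnostic is implied. Rank
  deficiency in an imputation model is tolerated (aliased columns get
  zero coefficients) since prediction, not inference, is the goal.

Pooling follows Rubin's rules: pooled estimate = mean;
total variance = within + (1 + 1/m) · between; degrees of freedom by the
Barnard–Rubin small-sample adjustment whenever a complete-data df is
available. Pooling is permutation-invariant in dataset order and reduces
correctly in the degenerate equal-estimates case (between-variance 0) —
both tested against closed-form arithmetic.

## The path model

Two binary outcomes (reading and numeracy resilient membership) share
one predictor set — all explanatory-to-outcome paths estimated — which
makes the path estimates equivalent to outcome-wise logistic
regressions; the package fits exactly that, per imputed dataset, in two
nested stages (explanatory only; plus socio-demographic covariates). A
four-category joint-outcome multinomial formulation, and residual
correlation between the two outcomes, are intentionally out of scope;
the latter is a known limitation of the two-equation factorization.

* **Link:** logit by default (probit available). Latent-response
  residual variance π²/3 (logit) or 1 (probit).
* **Standardized estimates:**
  $\tilde b_j = b_j\,\mathrm{SD}(x_j)/\mathrm{SD}(y^*)$ with
  $\mathrm{Var}(y^*) = \mathrm{Var}(\hat\eta) + \pi^2/3$. Binary
  predictors are standardized with their sample SD like any other
  column. Standard errors scale by the same factor (the variability of
  the SDs themselves is ignored, the conventional choice).
* **Pseudo-R²: McKelvey–Zavoina**,
  $\mathrm{Var}(\hat\eta)/(\mathrm{Var}(\hat\eta)+\pi^2/3)$ — chosen to
  be coherent with the latent-response standardization: with
  independent standardized predictors it converges to the sum of
  squared standardized effects, an identity the tests exercise. Other
  pseudo-R² definitions (McFadden, Nagelkerke) would give different
  numbers; none is asserted as comparable to any externally reported
  variance-explained figure.
* **VIF screen** before fitting: VIF$_j = 1/(1-R^2_j)$ from regressing
  predictor $j$ on the rest, threshold 2 (configurable); exceedance is
  an error by default, downgradable to a warning. Perfect collinearity
  reports an infinite VIF with a flag.
* **Separation** (a predictor perfectly predicting an outcome in any
  imputed dataset) is detected via non-convergence or runaway
  coefficients (|b| > 15 on the logit scale) and raised as an error
  naming the predictor, rather than returning meaningless estimates.

`simulate_binary_outcome_data()` inverts the standardization in closed
form — given target standardized effects $s$ with $S=\sum s^2 < 1$, raw
coefficients $b = s\sqrt{vS/(1-S)+v}$ reproduce $s$ exactly in the
population — providing ground truth for parameter-recovery tests
without circularity.

## Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances while remaining
quick on a single CPU: correlation-recovery and MAR-distribution checks
at n = 20 000; oracle-equivalence over 100 cohorts of n = 2 000;
parameter recovery at n = 5 000 with m = 5; the 24%-missingness
recovery at n = 5 000 with the full m = 40; the qualitative path-model
pattern over 50 replicates at study scale (n = 2118, ~780 vulnerable);
type-I calibration over 200 replicates. Every stochastic step is seeded:
cohorts and masking from `generator_config(seed)` (masking uses a fixed
offset of the same seed so the two draws are decoupled), imputation from
`imputation_config(seed)` via a single sequential RNG stream.

## Known limitations

* The predicted-score rule is a mean-rule: with symmetric noise and
  stratum-only regressors roughly half of each stratum is classified
  resilient by construction. The classification is therefore a relative
  ranking within stratum, not an absolute standard; alternative
  definitions (residual percentile bands, reliable-change indices) are
  extension points, not implemented.
* Two separate logistic equations ignore residual dependence between
  reading and numeracy resilience; pooled SEs are correct per equation
  but no joint test across outcomes is offered.
* The imputation engine is single-level; cohorts with substantial
  school-level clustering would need a multilevel imputation model.
* The generator's normality and homoscedasticity assumptions are
  conveniences; none of the acceptance evidence speaks to robustness
  under skewed or heteroscedastic real data.
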