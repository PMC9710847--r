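# resilgap

Identifying academically resilient children — and what explains them — in
longitudinal school cohorts.

Many children enter school with weak language and cognitive skills, yet a
substantial fraction of them close the gap by the middle primary years.
`resilgap` implements the full analysis pipeline for quantifying that
"closing the gap" pathway in child-level cohort data linking a
school-entry developmental measure (an AEDC-style teacher-rated
language/cognitive domain score) with later standardized achievement
(NAPLAN-style Grade-3 reading and numeracy scores on a 0–1000 scale):

1. **Stratification** — children are assigned to four school-entry
   percentile groups: lowest 10% (developmentally vulnerable), 10th–25th
   (at risk), 25th–50th, and the top 50% ("strong in Prep"). Everyone at
   or below the 50th percentile is *academically vulnerable*.
2. **Resilience classification** — ordinary least squares of Grade-3
   achievement on the three vulnerable-stratum indicators (reference =
   top-50% group) gives each stratum a predicted score

   *P* = *M*<sub>Top50</sub> − *β* · SD,

   where *M*<sub>Top50</sub> is the mean achievement of the top-50%
   group, *β* the outcome-standardized stratum coefficient (*β* = *b* /
   SD), and SD the full-sample standard deviation of the achievement
   score. A vulnerable child whose actual score is at or above the
   stratum's predicted score is *resilient*; below it,
   *ongoing-vulnerable*. With stratum-only regressors, *P* reduces
   exactly to the stratum's own mean — a property the test suite
   exploits as an independent oracle.
3. **Bivariate screening** — uncorrected Pearson chi-square tests and
   classical one-way ANOVAs compare resilient vs ongoing-vulnerable
   children on child, parenting and school factors; three-group
   achievement comparisons (ongoing, resilient, strong-in-Prep) use
   Bonferroni-corrected pairwise contrasts and grade-level benchmark
   flags.
4. **Missing data** — teacher-reported explanatory variables carry up
   to ~24% missingness. Multiple imputation by chained equations
   (predictive mean matching with Bayesian parameter draws; Bayesian
   logistic draws for binary variables) produces m = 40 completed
   datasets; estimates are pooled by Rubin's rules with Barnard–Rubin
   degrees of freedom.
5. **Path model** — reading and numeracy resilient-membership are
   jointly regressed (logit, probit optional) on the screened
   explanatory variables, then additionally on socio-demographic
   covariates. Estimates are reported on the latent-response
   standardized scale (std = *b* · SD(x) / SD(y\*), Var(y\*) =
   Var(η) + π²/3), with McKelvey–Zavoina pseudo-R² and a VIF < 2
   multicollinearity screen.

Because the cohort data such analyses run on are access-restricted, the
package ships a first-class synthetic-cohort generator
(`generate_cohort()`, `apply_mar_missingness()`) with a factor-structured
correlation engine over 34 mixed-type covariates, a four-stratum
achievement gradient, and a calibrated logistic missing-at-random
mechanism — every downstream stage is fully testable without restricted
data.

## Worked example

```r
library(resilgap)

cfg    <- generator_config(seed = 20201)   # 2118 children, default calibration
cohort <- generate_cohort(cfg)
split  <- assign_percentile_groups(cohort$entry_score)
fits   <- lapply(c("reading", "numeracy"), function(d)
  fit_baseline_regression(cohort, split, d))
pred   <- compute_predicted_scores(fits)
pred
#>     domain stratum predicted
#> 1  reading     V10   368.830
#> 2  reading  V10_25   402.708
#> 3  reading  V25_50   429.200
#> 4 numeracy     V10   338.593
#> 5 numeracy  V10_25   382.112
#> 6 numeracy  V25_50   411.980

labels <- classify_resilience(cohort, split, pred)
gradient_summary(labels)
#>     domain stratum   n n_resilient prop_resilient prop_ongoing
#> 1  reading     V10 212         111          0.524        0.476
#> 2  reading  V10_25 318         159          0.500        0.500
#> 3  reading  V25_50 529         252          0.476        0.524
#> 4 numeracy     V10 212          97          0.458        0.542
#> 5 numeracy  V10_25 318         154          0.484        0.516
#> 6 numeracy  V25_50 529         267          0.505        0.495
```

The predicted scores rise monotonically from the lowest-10% stratum to
the 25th–50th stratum in both domains — each stratum is held to its own
baseline, not a common bar. The resulting resilient/ongoing split is
close to 50/50 in *every* stratum: children with the greatest
school-entry vulnerability are about as likely to close their
(stratum-specific) gap as those just below the median, the gradient
pattern the classification is designed to expose.

## The analysis workflow

`analysis/` contains the pipeline as numbered drivers over the package
functions, writing all artifacts under `results/`:

```sh
Rscript analysis/01_simulate.R             # cohort + MAR masking
Rscript analysis/02_classify_resilience.R  # strata, predicted scores, labels
Rscript analysis/03_screen_groups.R        # demographics, 3-group ANOVA, screen
Rscript analysis/04_impute.R               # chained-equation imputation, m = 40
Rscript analysis/05_path_model.R           # pooled two-stage path model
Rscript analysis/06_report.R               # cross-footed JSON/CSV report
```

Stage 5 prints the pooled latent-response standardized estimates; under
the default calibration, teacher-rated attentional regulation and
directly assessed receptive vocabulary emerge as the only explanatory
variables significantly associated with resilient membership in *both*
achievement domains, with girls and sleep problems negatively associated
with numeracy resilience only.

## Vignette

`vignettes/resilience-methods.Rmd` documents the model and its
assumptions, the generator calibration, the imputation and pooling
machinery, the standardization conventions, and known limitations.
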