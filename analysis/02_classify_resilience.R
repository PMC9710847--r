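#!/usr/bin/env Rscript
# Stage 2: stratify school-entry scores and classify academic resilience.
#
# Children are assigned to the four percentile groups against
# norm-referenced cutpoints (the cohort is a positively selected sample
# scored against population norms, so the vulnerable share falls below
# 50%). Stratum-only baseline regressions of Grade-3 reading and
# numeracy on the entry strata give each vulnerable stratum its
# predicted score; a vulnerable child at or above the predicted score is
# resilient, below it ongoing-vulnerable.

suppressPackageStartupMessages(library(resilgap))

cohort <- read_cohort("results/cohort.csv")
split <- assign_percentile_groups(cohort$entry_score,
                                 cutpoints = norm_referenced_cutpoints())

fits <- lapply(c("reading", "numeracy"), function(d)
  fit_baseline_regression(cohort, split, d))
predicted <- compute_predicted_scores(fits)
labels <- classify_resilience(cohort, split, predicted)

cs <- cross_domain_summary(labels)
message(sprintf("vulnerable: %d / %d (%.2f%%)", cs$n_vulnerable, cs$n_total,
                cs$vulnerable_share_pct))
for (d in cs$domains)
  message(sprintf("%s: %d resilient (%.0f%% of vulnerable)", d,
                  cs$n_resilient[[d]], cs$resilient_pct[[d]]))
message(sprintf("resilient in at least one domain: %d (%.0f%%); in both: %d",
                cs$n_at_least_one, cs$at_least_one_pct, cs$n_both))

grp <- data.frame(child_id = cohort$child_id,
                  group = as.character(split$group),
                  vulnerable = split$vulnerable)
utils::write.csv(grp, "results/groups.csv", row.names = FALSE)
utils::write.csv(labels, "results/labels.csv", row.names = FALSE, na = "")
audit <- lapply(fits, function(f)
  list(domain = f$domain, reference_mean = f$reference_mean,
       overall_sd = f$overall_sd, b = as.list(f$unstandardized),
       beta = as.list(f$betas)))
jsonlite::write_json(list(fits = audit, predicted = predicted,
                          cutpoints = as.list(split$cutpoints)),
                     "results/predicted.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, dataframe = "rows")
grad <- gradient_summary(labels)
utils::write.csv(grad, "results/gradient.csv", row.names = FALSE)
message("wrote results/groups.csv, labels.csv, predicted.json, gradient.csv")
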