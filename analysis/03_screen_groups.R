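#!/usr/bin/env Rscript
# Stage 3: bivariate group comparisons.
#
# Three surfaces: (a) socio-demographic differences between resilient
# and ongoing-vulnerable children (chi-square for categorical, ANOVA for
# socio-economic position); (b) the three-group achievement comparison
# (ongoing, resilient, strong-in-Prep) with Bonferroni-corrected
# pairwise tests and grade-level benchmark flags; (c) the explanatory
# variable screen that selects candidates for the path model.

suppressPackageStartupMessages(library(resilgap))

cohort <- read_cohort("results/cohort.csv")
labels <- utils::read.csv("results/labels.csv", na.strings = "",
                          stringsAsFactors = FALSE)
labels$group <- factor(labels$group,
                       levels = c("V10", "V10_25", "V25_50", "TOP50"),
                       ordered = TRUE)
attr(labels, "domains") <- c("reading", "numeracy")
class(labels) <- c("resilience_labels", "data.frame")

# (a) socio-demographics of resilient vs ongoing-vulnerable
demo <- screen_explanatory_variables(cohort, labels,
                                     c("gender", "indigenous", "lote", "sep"))
utils::write.csv(demo, "results/demographics.csv", row.names = FALSE, na = "")

# (b) three-group achievement comparison and benchmark flags
# Benchmark scores are configuration, not data: grade-level equivalents
# on the synthetic score scale.
benchmarks <- c(reading = 420, numeracy = 400)
for (d in c("reading", "numeracy")) {
  cmp <- three_group_comparison(cohort, labels, d)
  message(sprintf("%s omnibus F(%d, %d) = %.1f", d, cmp$omnibus$df[["num"]],
                  cmp$omnibus$df[["den"]], cmp$omnibus$statistic))
  for (i in seq_len(nrow(cmp$pairwise)))
    message(sprintf("  %s vs %s: diff = %+.1f, Bonferroni p = %.3g",
                    cmp$pairwise$group2[i], cmp$pairwise$group1[i],
                    cmp$pairwise$mean_diff[i], cmp$pairwise$p_bonferroni[i]))
  utils::write.csv(cmp$pairwise, sprintf("results/three_group_%s.csv", d),
                   row.names = FALSE)
}
flags <- benchmark_flags(group_achievement_means(cohort, labels), benchmarks)
utils::write.csv(flags, "results/benchmark_flags.csv", row.names = FALSE)
above <- flags$group[flags$above_benchmark == 1 & flags$domain == "reading"]
message("reading groups at/above the grade-level benchmark: ",
        paste(above, collapse = ", "))

# (c) explanatory screen (complete-case per variable)
inv <- cohort_variable_inventory()$name
explanatory <- setdiff(inv, c("gender", "indigenous", "lote", "sep",
                              grep("_w2$", inv, value = TRUE)))
screen <- screen_explanatory_variables(cohort, labels, explanatory)
utils::write.csv(screen, "results/screen.csv", row.names = FALSE, na = "")
kept <- unique(screen$variable[screen$sig_05 %in% TRUE])
writeLines(kept, "results/screened_variables.txt")
message(sprintf("screened %d variables; %d pass at p < .05 in either domain: %s",
                length(explanatory), length(kept), paste(kept, collapse = ", ")))
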