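#!/usr/bin/env Rscript
# Stage 6: assemble the full machine-readable report.
#
# Collects every stage's outputs into one JSON report plus CSV tables,
# cross-footing all counts, and stamps it with a provenance manifest
# (config hash, seeds, input digests).

suppressPackageStartupMessages(library(resilgap))

cohort <- read_cohort("results/cohort.csv")
labels <- utils::read.csv("results/labels.csv", na.strings = "",
                          stringsAsFactors = FALSE)
labels$group <- factor(labels$group,
                       levels = c("V10", "V10_25", "V25_50", "TOP50"),
                       ordered = TRUE)
attr(labels, "domains") <- c("reading", "numeracy")
class(labels) <- c("resilience_labels", "data.frame")

predicted <- jsonlite::read_json("results/predicted.json",
                                 simplifyVector = TRUE)$predicted
gradient <- utils::read.csv("results/gradient.csv")
demographics <- utils::read.csv("results/demographics.csv", na.strings = "")
screen <- utils::read.csv("results/screen.csv", na.strings = "")

manifest <- run_manifest(
  config = list(generator = "results/generator_config.yaml"),
  seeds = c(generator = 20201L, imputation = 40411L),
  input_files = c("results/cohort.csv", "results/labels.csv"))

report <- build_report(labels, predicted = predicted, gradient = gradient,
                       demographics = demographics, screen = screen,
                       benchmarks = c(reading = 420, numeracy = 400),
                       cohort = cohort, manifest = manifest)
out <- write_report(report, "results/report")
message("report written to ", out)
message(sprintf("sample: %d vulnerable (%s%%), %d strong in Prep (%s%%)",
                report$sample$n_vulnerable, report$sample$vulnerable_share_pct,
                report$sample$n_strong, report$sample$strong_share_pct))
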