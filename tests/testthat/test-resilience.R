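test_that("covariate-free stratum coefficients equal group-mean differences", {
  coh <- generate_cohort(complete_config(n = 3000, seed = 14))
  split <- assign_percentile_groups(coh$entry_score)
  for (d in c("reading", "numeracy")) {
    fit <- fit_baseline_regression(coh, split, d)
    gm <- tapply(coh[[d]], split$group, mean)  # group-by oracle
    expect_equal(unname(fit$unstandardized),
                 as.vector(gm[c("V10", "V10_25", "V25_50")] - gm["TOP50"]),
                 tolerance = 1e-9)
    expect_equal(fit$reference_mean, as.vector(gm["TOP50"]), tolerance = 1e-9)
    expect_equal(fit$overall_sd, sd(coh[[d]]), tolerance = 1e-12)
    # standardization identity beta = b / overall_sd
    expect_equal(fit$betas, fit$unstandardized / fit$overall_sd)
  }
})

test_that("degenerate variance and rank deficiency are errors", {
  coh <- generate_cohort(complete_config(n = 200, seed = 15))
  split <- assign_percentile_groups(coh$entry_score)
  coh$reading <- 500
  expect_error(fit_baseline_regression(coh, split, "reading"), "SD")
  coh2 <- generate_cohort(complete_config(n = 200, seed = 15))
  coh2$dup <- coh2$sep
  expect_error(fit_baseline_regression(coh2, split, "reading",
                                       covariates = c("sep", "dup")),
               "collinear")
})

test_that("configured stratum offsets are recovered at large n", {
  cfg <- zero_effect_config(n = 20000, seed = 16)
  cfg$stratum_effects <- list(reading = c(V10 = -80, V10_25 = -55, V25_50 = -30),
                              numeracy = c(V10 = -80, V10_25 = -55, V25_50 = -30))
  coh <- generate_cohort(cfg)
  split <- assign_percentile_groups(coh$entry_score)
  fit <- fit_baseline_regression(coh, split, "reading")
  expect_lt(max(abs(fit$unstandardized - c(-80, -55, -30))), 3)
})

test_that("predicted scores equal stratum means in the covariate-free fit", {
  coh <- generate_cohort(complete_config(n = 2500, seed = 17))
  split <- assign_percentile_groups(coh$entry_score)
  fit <- fit_baseline_regression(coh, split, "reading")
  pred <- compute_predicted_scores(fit)
  gm <- tapply(coh$reading, split$group, mean)
  expect_equal(pred$predicted, as.vector(gm[as.character(pred$stratum)]),
               tolerance = 1e-9)
  # P = reference_mean + beta * SD, and a zero beta leaves P at the reference
  fit0 <- fit
  fit0$betas[] <- 0
  expect_equal(compute_predicted_scores(fit0)$predicted,
               rep(fit$reference_mean, 3))
})

test_that("predicted scores rise monotonically from V10 to V25_50", {
  coh <- generate_cohort(complete_config(n = 5000, seed = 18))
  res <- classify_pipeline(coh)
  for (d in c("reading", "numeracy")) {
    p <- res$predicted$predicted[res$predicted$domain == d]
    expect_true(all(diff(p) > 0), label = d)
  }
})

test_that("a child whose actual score equals the predicted score is resilient", {
  coh <- data.frame(child_id = sprintf("C%03d", 1:100),
                    entry_score = 1:100, reading = rnorm(100, 420, 10))
  split <- assign_percentile_groups(coh$entry_score)
  pred <- data.frame(domain = "reading",
                     stratum = factor(c("V10", "V10_25", "V25_50"),
                                      levels = stratum_levels),
                     predicted = c(400, 420, 440))
  class(pred) <- c("predicted_score_table", "data.frame")
  coh$reading[1] <- 400          # V10 child exactly at the predicted score
  coh$reading[2] <- 400 - 1e-9   # just below
  labels <- classify_resilience(coh, split, pred)
  expect_equal(labels$reading_resilient[1], 1L)
  expect_equal(labels$reading_resilient[2], 0L)
  expect_true(all(is.na(labels$reading_resilient[split$vulnerable == 0])))
})

test_that("vulnerable children with missing achievement are excluded with a count", {
  coh <- generate_cohort(complete_config(n = 500, seed = 19))
  res <- classify_pipeline(coh)
  coh$reading[which(res$split$vulnerable == 1)[1:7]] <- NA
  expect_warning(
    labels <- classify_resilience(coh, res$split, res$predicted),
    "7 vulnerable children")
  expect_equal(attr(labels, "excluded")[["reading"]], 7L)
  expect_equal(sum(is.na(labels$reading_resilient[res$split$vulnerable == 1])), 7)
})

test_that("classification matches the actual-vs-stratum-mean oracle", {
  coh <- generate_cohort(complete_config(n = 2000, seed = 20))
  res <- classify_pipeline(coh)
  for (d in c("reading", "numeracy")) {
    gm <- tapply(coh[[d]], res$split$group, mean)
    oracle <- ifelse(res$split$vulnerable == 1,
                     as.integer(coh[[d]] >= gm[as.character(res$split$group)]),
                     NA_integer_)
    expect_identical(res$labels[[paste0(d, "_resilient")]], oracle)
  }
})

test_that("resilience labels are invariant to affine achievement rescaling", {
  coh <- generate_cohort(complete_config(n = 1500, seed = 22))
  base <- classify_pipeline(coh)
  coh2 <- coh
  coh2$reading <- 3.7 * coh$reading + 112
  coh2$numeracy <- 3.7 * coh$numeracy + 112
  resc <- classify_pipeline(coh2)
  expect_identical(base$labels$reading_resilient, resc$labels$reading_resilient)
  expect_identical(base$labels$numeracy_resilient, resc$labels$numeracy_resilient)
  # reference mean and raw coefficients transform consistently
  expect_equal(resc$fits[[1]]$reference_mean,
               3.7 * base$fits[[1]]$reference_mean + 112, tolerance = 1e-9)
  expect_equal(resc$fits[[1]]$unstandardized,
               3.7 * base$fits[[1]]$unstandardized, tolerance = 1e-9)
})

test_that("gradient proportions come from counting and sum to one", {
  coh <- generate_cohort(complete_config(n = 2000, seed = 23))
  res <- classify_pipeline(coh)
  gs <- gradient_summary(res$labels)
  expect_equal(gs$prop_resilient + gs$prop_ongoing,
               rep(1, nrow(gs))[seq_len(nrow(gs))], tolerance = 1e-12,
               ignore_attr = TRUE)
  # brute-force filter-and-count oracle
  for (i in which(gs$stratum %in% c("V10", "V25_50") & gs$domain == "reading")) {
    lab <- res$labels$reading_resilient
    in_s <- res$labels$group == gs$stratum[i] & !is.na(lab)
    expect_equal(gs$n_resilient[i], sum(lab[in_s]))
    expect_equal(gs$prop_resilient[i], mean(lab[in_s]))
  }
  # empty strata are undefined, not zero
  gs_top <- gs[gs$stratum == "TOP50", ]
  expect_true(all(is.na(gs_top$prop_resilient)))
})

test_that("near-even resilient/ongoing splits arise in every stratum", {
  # With P equal to the stratum mean and symmetric noise, each stratum splits
  # close to 50/50 between resilient and ongoing-vulnerable.
  coh <- generate_cohort(zero_effect_config(n = 20000, seed = 24))
  res <- classify_pipeline(coh)
  gs <- gradient_summary(res$labels)
  vul <- gs[gs$stratum != "TOP50", ]
  expect_true(all(abs(vul$prop_resilient - 0.5) < 0.05))
})

test_that("cross-domain categories satisfy the partition identities", {
  coh <- generate_cohort(complete_config(n = 3000, seed = 25))
  res <- classify_pipeline(coh)
  cs <- cross_domain_summary(res$labels)
  expect_equal(cs$n_both + cs$n_only[["reading"]],
               unname(cs$n_resilient["reading"]))
  expect_equal(cs$n_both + cs$n_only[["numeracy"]],
               unname(cs$n_resilient["numeracy"]))
  expect_equal(cs$n_both + sum(cs$n_only), cs$n_at_least_one)
  expect_equal(cs$n_at_least_one + cs$n_neither, cs$n_vulnerable)
})
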