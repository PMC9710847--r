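test_that("chi-square statistic matches cell-by-cell brute force", {
  set.seed(30)
  tab <- matrix(rpois(12, 40) + 1, 3, 4)
  got <- pearson_chi_square(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(got$df, 6)
  expect_equal(got$p, pchisq(got$statistic, 6, lower.tail = FALSE))
  # invariant to row/column permutation
  perm <- pearson_chi_square(tab[c(3, 1, 2), c(2, 4, 1, 3)])
  expect_equal(perm$statistic, got$statistic, tolerance = 1e-12)
})

test_that("identical row distributions give zero chi-square; degenerate tables error", {
  expect_equal(pearson_chi_square(rbind(c(10, 20, 30), c(20, 40, 60)))$statistic,
               0, tolerance = 1e-12)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(3, 5))), "margin")
  expect_warning(pearson_chi_square(rbind(c(1, 120), c(1, 150))), "below 1")
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(31)
  v <- c(rnorm(40, 0, 2), rnorm(55, 0.7, 2))
  g <- rep(c("a", "b"), c(40, 55))
  got <- one_way_anova(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)  # independent oracle
  expect_equal(got$statistic, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)
  expect_equal(unname(got$df), c(1, 93))
})

test_that("ANOVA handles constants, missing data and invariances", {
  expect_equal(one_way_anova(rep(5, 20), rep(c("a", "b"), 10))$statistic, 0)
  set.seed(32)
  v <- rnorm(60); g <- rep(letters[1:3], 20)
  v[c(3, 10)] <- NA
  expect_message(got <- one_way_anova(v, g), "dropped 2")
  expect_equal(got$n_dropped, 2)
  # F unchanged under shift and scale
  base <- suppressMessages(one_way_anova(v, g))
  expect_equal(suppressMessages(one_way_anova(3 * v + 11, g))$statistic,
               base$statistic, tolerance = 1e-10)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), "at least 2 obs")
})

test_that("a 0.5 SD shift is detected in >90% of replicates at Table-4-like sizes", {
  set.seed(33)
  rejected <- replicate(500, {
    v <- c(rnorm(300, 0), rnorm(480, 0.5))
    g <- rep(c("r", "o"), c(300, 480))
    one_way_anova(v, g)$p < 0.05
  })
  expect_gt(mean(rejected), 0.9)
})

test_that("three-group comparison applies Bonferroni over the three pairs", {
  coh <- generate_cohort(complete_config(n = 1200, seed = 34))
  res <- classify_pipeline(coh)
  cmp <- three_group_comparison(coh, res$labels, "reading")
  expect_equal(nrow(cmp$pairwise), 3)
  expect_equal(cmp$pairwise$p_bonferroni,
               pmin(1, 3 * cmp$pairwise$p_raw))  # arithmetic oracle
  expect_true(all(cmp$pairwise$p_bonferroni >= cmp$pairwise$p_raw))
})

test_that("identical constant groups give F = 0 and adjusted p = 1", {
  n <- 90
  coh <- data.frame(child_id = as.character(1:n), entry_score = 1:n,
                    reading = rep(444, n))
  split <- assign_percentile_groups(coh$entry_score)
  lab <- data.frame(child_id = coh$child_id, group = split$group,
                    vulnerable = split$vulnerable,
                    reading_resilient = ifelse(split$vulnerable == 1,
                                               rep_len(0:1, sum(split$vulnerable)),
                                               NA_integer_))
  attr(lab, "domains") <- "reading"
  class(lab) <- c("resilience_labels", "data.frame")
  cmp <- three_group_comparison(coh, lab, "reading")
  expect_equal(cmp$omnibus$statistic, 0)
  expect_equal(cmp$pairwise$p_bonferroni, rep(1, 3))
})

test_that("equal-achievement resilient and strong groups are separated from ongoing", {
  # resilient and strong-in-prep drawn from one distribution; ongoing 60 points
  # lower: ongoing differs from both, resilient vs strong does not, in >= 90%
  set.seed(35)
  hits <- replicate(200, {
    n <- 500
    coh <- data.frame(child_id = as.character(1:(3 * n)),
                      entry_score = 1:(3 * n),
                      reading = c(rnorm(2 * n, 430, 70), rnorm(n, 370, 70)))
    grp <- c(rep("strong", n), rep("resilient", n), rep("ongoing", n))
    # map onto a labels object: strong = TOP50, others vulnerable
    lab <- data.frame(child_id = coh$child_id,
                      group = factor(ifelse(grp == "strong", "TOP50", "V25_50"),
                                     levels = stratum_levels, ordered = TRUE),
                      vulnerable = as.integer(grp != "strong"),
                      reading_resilient = ifelse(grp == "strong", NA_integer_,
                                                 as.integer(grp == "resilient")))
    attr(lab, "domains") <- "reading"
    class(lab) <- c("resilience_labels", "data.frame")
    cmp <- three_group_comparison(coh, lab, "reading")
    pw <- cmp$pairwise
    p_ong_res <- pw$p_bonferroni[pw$group1 == "ongoing_vulnerable" &
                                   pw$group2 == "resilient"]
    p_ong_str <- pw$p_bonferroni[pw$group1 == "ongoing_vulnerable" &
                                   pw$group2 == "strong_in_prep"]
    p_res_str <- pw$p_bonferroni[pw$group1 == "resilient" &
                                   pw$group2 == "strong_in_prep"]
    (p_ong_res < 0.05) && (p_ong_str < 0.05) && (p_res_str >= 0.05)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("benchmark flags use the at-or-above convention and match a raw scan", {
  gm <- data.frame(group = c("ongoing_vulnerable", "resilient"),
                   domain = "reading", mean = c(420, 440))
  flags <- benchmark_flags(gm, c(reading = 420))
  expect_equal(flags$above_benchmark, c(1L, 1L))
  flags2 <- benchmark_flags(gm, c(reading = 430))
  expect_equal(flags2$above_benchmark, c(0L, 1L))
  expect_error(benchmark_flags(gm, c(numeracy = 400)), "benchmark")
  # group-by oracle on a real cohort
  coh <- generate_cohort(complete_config(n = 1000, seed = 36))
  res <- classify_pipeline(coh)
  gm3 <- group_achievement_means(coh, res$labels)
  flags3 <- benchmark_flags(gm3, c(reading = 420, numeracy = 400))
  for (i in seq_len(nrow(flags3))) {
    lab <- res$labels[[paste0(flags3$domain[i], "_resilient")]]
    grp <- rep(NA_character_, nrow(coh))
    grp[res$labels$vulnerable == 0] <- "strong_in_prep"
    grp[!is.na(lab) & lab == 0] <- "ongoing_vulnerable"
    grp[!is.na(lab) & lab == 1] <- "resilient"
    m <- mean(coh[[flags3$domain[i]]][grp == flags3$group[i]], na.rm = TRUE)
    expect_equal(flags3$mean[i], m, tolerance = 1e-9)
    expect_equal(flags3$above_benchmark[i],
                 as.integer(m >= flags3$benchmark[i]))
  }
})

test_that("the explanatory screen has the variables-by-domains shape", {
  coh <- generate_cohort(complete_config(n = 1500, seed = 37))
  res <- classify_pipeline(coh)
  vars <- c("attentional_regulation", "vocabulary", "school_sector",
            "maternal_anger")
  scr <- screen_explanatory_variables(coh, res$labels, vars)
  expect_equal(nrow(scr), length(vars) * 2)
  expect_setequal(unique(scr$domain), c("reading", "numeracy"))
  expect_equal(scr$test[scr$variable == "school_sector"],
               rep("chi_square", 2))
  expect_equal(scr$test[scr$variable == "vocabulary"], rep("anova", 2))
  # constant variables are reported untestable, not dropped
  coh$const <- 1
  scr2 <- screen_explanatory_variables(coh, res$labels, c("const", "vocabulary"))
  expect_equal(scr2$note[scr2$variable == "const"], rep("untestable: constant", 2))
  expect_equal(nrow(scr2), 4)
})

test_that("a truly different variable is flagged and a null one at ~5%", {
  set.seed(38)
  # 2.2-point shift on an SD-3.5 scale at n = 300/480: flagged at p < .01
  power_hits <- replicate(100, {
    v <- c(rnorm(480, 16.7, 3.5), rnorm(300, 18.9, 3.5))
    g <- rep(c("o", "r"), c(480, 300))
    one_way_anova(v, g)$p < 0.01
  })
  expect_gte(mean(power_hits), 0.95)
  null_hits <- replicate(400, {
    v <- rnorm(780, 10, 2)
    g <- rep(c("o", "r"), c(480, 300))
    one_way_anova(v, g)$p < 0.05
  })
  expect_gte(mean(null_hits), 0.02)
  expect_lte(mean(null_hits), 0.09)
})
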