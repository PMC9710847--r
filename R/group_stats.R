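#' Pearson chi-square test of independence on a contingency table
#'
#' Uncorrected Pearson statistic `sum (O - E)^2 / E` with expected
#' counts from the row/column margins and `df = (r-1)(c-1)`; no Yates
#' continuity correction (the uncorrected statistic is what reproduces
#' printed two-by-two comparisons in this literature). Expected counts
#' below one trigger a warning but the statistic is still returned; a
#' zero margin is an error.
#'
#' @param table Integer matrix of counts, at least 2x2.
#' @return List of class `chi_square_test`: `statistic`, `df`, `p`,
#'   `expected`, `observed`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  assert_that(all(table >= 0) && !anyNA(table), "counts must be non-negative")
  assert_that(nrow(table) >= 2 && ncol(table) >= 2,
              "contingency table must be at least 2x2")
  rm_ <- rowSums(table); cm <- colSums(table)
  assert_that(all(rm_ > 0) && all(cm > 0), "zero margin in contingency table")
  expected <- outer(rm_, cm) / sum(table)
  if (any(expected < 1))
    warn_("%d expected counts below 1; chi-square approximation unreliable",
          sum(expected < 1))
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = unname(ht$p.value),
                 expected = expected, observed = table),
            class = "chi_square_test")
}

#' Classical one-way analysis of variance
#'
#' Between/within decomposition under the equal-variance assumption.
#' Rows with a missing value or group are dropped (count reported in the
#' result). With exactly two groups the F statistic equals the square of
#' the pooled-variance t statistic. When there is no between-group
#' variability at all (all values identical) F is reported as 0.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List of class `anova_result`: `statistic` (F), `df` (num,
#'   den), `p`, `group_stats` (n, mean, sd per group), `n_dropped`.
#' @export
one_way_anova <- function(values, groups) {
  assert_that(length(values) == length(groups),
              "values and groups differ in length")
  keep <- !is.na(values) & !is.na(groups)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("one_way_anova: dropped %d incomplete observations", n_dropped))
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  assert_that(k >= 2, "need at least 2 groups")
  counts <- table(groups)
  assert_that(all(counts >= 2),
              "every group needs at least 2 observations (offending: %s)",
              paste(names(counts)[counts < 2], collapse = ", "))
  av <- withCallingHandlers(
    stats::anova(stats::lm(values ~ groups)),
    warning = function(w) {
      # the perfect-fit warning fires exactly in the degenerate constant
      # case we handle explicitly below
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss <- av$`Sum Sq`
  # no between-group variability (identical values up to float noise):
  # F defined as 0, not 0/0
  if (stats::var(values) == 0 || ss[1] <= 1e-12 * sum(ss)) {
    f <- 0; p <- 1
  } else {
    f <- av$`F value`[1]; p <- av$`Pr(>F)`[1]
  }
  gs <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  structure(list(statistic = f,
                 df = c(num = av$Df[1], den = av$Df[2]),
                 p = p, group_stats = gs, n_dropped = n_dropped),
            class = "anova_result")
}

#' Three-group achievement comparison with Bonferroni correction
#'
#' Compares achievement in a domain across the ongoing-vulnerable,
#' resilient, and strong-in-Prep groups: omnibus one-way ANOVA plus the
#' three pairwise pooled-variance t comparisons, each p-value multiplied
#' by 3 and capped at 1 (the Bonferroni family is the three pairwise
#' contrasts within a domain).
#'
#' @param table A `cohort_table`.
#' @param labels A `resilience_labels` for the same rows.
#' @param domain Achievement column name.
#' @return List of class `three_group_comparison`: `omnibus`
#'   (`anova_result`), `pairwise` (data frame with `group1`, `group2`,
#'   `mean_diff`, `p_raw`, `p_bonferroni`), `group_stats`.
#' @export
three_group_comparison <- function(table, labels, domain) {
  lab <- labels[[paste0(domain, "_resilient")]]
  grp <- rep(NA_character_, nrow(table))
  grp[labels$vulnerable == 0L] <- "strong_in_prep"
  grp[!is.na(lab) & lab == 0L] <- "ongoing_vulnerable"
  grp[!is.na(lab) & lab == 1L] <- "resilient"
  keep <- !is.na(grp) & !is.na(table[[domain]])
  values <- table[[domain]][keep]
  grp <- factor(grp[keep],
                levels = c("ongoing_vulnerable", "resilient", "strong_in_prep"))
  counts <- table(grp)
  empty <- names(counts)[counts == 0]
  assert_that(length(empty) == 0, "empty group: %s", paste(empty, collapse = ", "))
  omnibus <- one_way_anova(values, grp)
  pairs <- utils::combn(levels(grp), 2)
  pw <- do.call(rbind, apply(pairs, 2, function(pr) {
    v1 <- values[grp == pr[1]]; v2 <- values[grp == pr[2]]
    if (stats::var(v1) == 0 && stats::var(v2) == 0 && mean(v1) == mean(v2)) {
      p_raw <- 1  # degenerate: identical constants, no evidence either way
    } else {
      p_raw <- stats::t.test(v2, v1, var.equal = TRUE)$p.value
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               mean_diff = mean(v2) - mean(v1),
               p_raw = p_raw,
               p_bonferroni = min(1, 3 * p_raw),
               stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  structure(list(domain = domain, omnibus = omnibus, pairwise = pw,
                 group_stats = omnibus$group_stats),
            class = "three_group_comparison")
}

#' Flag group means against grade-level benchmark scores
#'
#' Marks each group-by-domain mean as at or above the supplied published
#' grade-level equivalent score (at-or-above convention: a mean exactly
#' equal to the benchmark counts as above).
#'
#' @param group_means Data frame with columns `group`, `domain`, `mean`.
#' @param benchmarks Named numeric vector, one benchmark score per
#'   domain.
#' @return The input with `benchmark` and `above_benchmark` columns.
#' @export
benchmark_flags <- function(group_means, benchmarks) {
  need <- unique(group_means$domain)
  missing <- setdiff(need, names(benchmarks))
  assert_that(length(missing) == 0, "no benchmark supplied for domain(s): %s",
              paste(missing, collapse = ", "))
  group_means$benchmark <- unname(benchmarks[group_means$domain])
  group_means$above_benchmark <-
    as.integer(group_means$mean >= group_means$benchmark)
  group_means
}

#' Mean achievement per resilience group
#'
#' Convenience builder for [benchmark_flags()]: mean achievement of the
#' ongoing-vulnerable, resilient and strong-in-Prep groups per domain.
#'
#' @param table A `cohort_table`.
#' @param labels A `resilience_labels`.
#' @param domains Achievement column names.
#' @return Data frame `group`, `domain`, `n`, `mean`, `sd`.
#' @export
group_achievement_means <- function(table, labels,
                                    domains = attr(labels, "domains")) {
  do.call(rbind, lapply(domains, function(d) {
    lab <- labels[[paste0(d, "_resilient")]]
    grp <- rep(NA_character_, nrow(table))
    grp[labels$vulnerable == 0L] <- "strong_in_prep"
    grp[!is.na(lab) & lab == 0L] <- "ongoing_vulnerable"
    grp[!is.na(lab) & lab == 1L] <- "resilient"
    keep <- !is.na(grp) & !is.na(table[[d]])
    agg <- do.call(rbind, lapply(
      c("ongoing_vulnerable", "resilient", "strong_in_prep"),
      function(g) {
        v <- table[[d]][keep & grp == g]
        data.frame(group = g, domain = d, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    agg
  }))
}

#' Bivariate screening of explanatory variables
#'
#' For each explanatory variable and achievement domain, compares the
#' resilient and ongoing-vulnerable groups: continuous variables with a
#' one-way ANOVA, binary/categorical ones with an uncorrected Pearson
#' chi-square on the group-by-level contingency table. Complete-case per
#' variable. Constant variables are recorded as untestable rather than
#' silently dropped. Significance is flagged at 0.05 and 0.01 without
#' multiplicity correction (screening, not inference).
#'
#' @param table A `cohort_table`.
#' @param labels A `resilience_labels`.
#' @param variables Character vector of explanatory columns.
#' @param domains Achievement domains to screen against.
#' @param categorical Optional character vector forcing variables to be
#'   treated as categorical; by default variables with at most 2
#'   distinct observed values are.
#' @return Data frame with one row per variable x domain: `variable`,
#'   `domain`, `test`, `statistic`, `df`, `p`, `mean_resilient`,
#'   `mean_ongoing`, `sig_05`, `sig_01`, `note`.
#' @export
screen_explanatory_variables <- function(table, labels, variables,
                                         domains = attr(labels, "domains"),
                                         categorical = NULL) {
  missing <- setdiff(variables, colnames(table))
  assert_that(length(missing) == 0, "variables not in table: %s",
              paste(missing, collapse = ", "))
  rows <- list()
  for (d in domains) {
    lab <- labels[[paste0(d, "_resilient")]]
    grp <- ifelse(is.na(lab), NA_character_,
                  ifelse(lab == 1L, "resilient", "ongoing_vulnerable"))
    for (v in variables) {
      x <- table[[v]]
      keep <- !is.na(x) & !is.na(grp)
      xv <- x[keep]; gv <- grp[keep]
      row <- data.frame(variable = v, domain = d, test = NA_character_,
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        mean_resilient = NA_real_, mean_ongoing = NA_real_,
                        sig_05 = NA, sig_01 = NA, note = "",
                        stringsAsFactors = FALSE)
      if (length(unique(xv)) < 2) {
        row$note <- "untestable: constant"
      } else if (v %in% categorical ||
                 (!is.numeric(xv) || length(unique(xv)) <= 2)) {
        ct <- table(gv, xv)
        ht <- pearson_chi_square(ct)
        row$test <- "chi_square"
        row$statistic <- ht$statistic; row$df <- ht$df; row$p <- ht$p
        if (is.numeric(xv)) {
          row$mean_resilient <- mean(xv[gv == "resilient"])
          row$mean_ongoing <- mean(xv[gv == "ongoing_vulnerable"])
        }
      } else {
        ht <- one_way_anova(xv, gv)
        row$test <- "anova"
        row$statistic <- ht$statistic; row$df <- ht$df[["num"]]; row$p <- ht$p
        row$mean_resilient <- ht$group_stats$mean[ht$group_stats$group == "resilient"]
        row$mean_ongoing <-
          ht$group_stats$mean[ht$group_stats$group == "ongoing_vulnerable"]
      }
      if (!is.na(row$p)) {
        row$sig_05 <- row$p < 0.05
        row$sig_01 <- row$p < 0.01
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
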