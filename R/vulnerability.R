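#' Assign four-level school-entry percentile groups
#'
#' Stratifies children on the school-entry developmental score into the
#' four conventional percentile groups: lowest 10% (`V10`,
#' "developmentally vulnerable"), 10th-25th (`V10_25`, "at risk"),
#' 25th-50th (`V25_50`), and top 50% (`TOP50`, "strong in Prep"). A
#' child exactly at a cutpoint falls in the lower group (at-or-below
#' convention), so `vulnerable == 1` means at or below the 50th
#' percentile. By default the cutpoints are the empirical 10th/25th/50th
#' percentiles of the sample (type-7 quantiles); externally published
#' norm cutpoints may be supplied instead.
#'
#' @param entry_score Numeric vector, fully observed.
#' @param cutpoints Optional strictly ascending numeric vector of three
#'   score thresholds (10th, 25th, 50th percentile scores).
#' @return An object of class `vulnerability_split`: list with `group`
#'   (ordered factor over `V10 < V10_25 < V25_50 < TOP50`), `vulnerable`
#'   (integer 0/1), and `cutpoints`.
#' @export
assign_percentile_groups <- function(entry_score, cutpoints = NULL) {
  assert_that(is.numeric(entry_score) && length(entry_score) > 0,
              "entry_score must be a non-empty numeric vector")
  assert_that(!anyNA(entry_score), "entry_score must be fully observed")
  assert_that(length(unique(entry_score)) >= 4,
              "fewer than 4 distinct entry scores: strata degenerate")
  if (is.null(cutpoints)) {
    cutpoints <- stats::quantile(entry_score, c(0.10, 0.25, 0.50),
                                 type = 7, names = FALSE)
  } else {
    assert_that(length(cutpoints) == 3 && all(diff(cutpoints) > 0),
                "cutpoints must be three strictly ascending thresholds")
  }
  names(cutpoints) <- c("p10", "p25", "p50")
  idx <- findInterval(entry_score, cutpoints, left.open = TRUE) + 1L
  group <- factor(STRATUM_LEVELS[idx], levels = STRATUM_LEVELS, ordered = TRUE)
  structure(list(group = group,
                 vulnerable = as.integer(group != "TOP50"),
                 cutpoints = cutpoints),
            class = "vulnerability_split")
}

#' @export
print.vulnerability_split <- function(x, ...) {
  cat("School-entry percentile groups\n")
  print(table(x$group))
  cat(sprintf("vulnerable: %d / %d (%.2f%%)\n", sum(x$vulnerable),
              length(x$vulnerable), 100 * mean(x$vulnerable)))
  cat("cutpoints:", paste(sprintf("%s=%.4g", names(x$cutpoints), x$cutpoints),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Norm-referenced cutpoints for a standard-normal entry score
#'
#' When stratification should follow external population norms rather
#' than sample-internal percentiles (e.g. a positively selected analytic
#' sample scored against national percentile bands), the cutpoints fall
#' at population quantiles. This helper returns the three thresholds for
#' a standard-normal latent entry score such that the expected
#' vulnerable share equals `vulnerable_share` while preserving the
#' population 10:15:25 ratio between the three vulnerable strata.
#'
#' @param vulnerable_share Expected proportion at or below the top
#'   cutpoint (default 0.3687, a typical share for a positively selected
#'   cohort scored against national norms).
#' @return Numeric vector of three ascending cutpoints.
#' @export
norm_referenced_cutpoints <- function(vulnerable_share = 0.3687) {
  assert_that(vulnerable_share > 0 && vulnerable_share < 1,
              "vulnerable_share must be in (0, 1)")
  stats::qnorm(vulnerable_share * c(10, 25, 50) / 50)
}
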