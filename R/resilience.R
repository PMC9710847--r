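#' Baseline regression of achievement on school-entry strata
#'
#' Ordinary least squares of a Grade-3 achievement domain on the three
#' vulnerable-stratum indicators (reference = TOP50), optionally plus
#' covariates for sensitivity analysis. Returns the raw stratum
#' coefficients `b`, the outcome-standardized coefficients
#' `beta = b / overall_sd` (standardized with respect to the dependent
#' variable only; the indicators stay raw), the TOP50 reference mean,
#' and the full-sample SD of the achievement score. With no covariates,
#' `b` for a stratum equals that stratum's mean minus the TOP50 mean.
#'
#' @param table A `cohort_table` (or data frame with the domain column).
#' @param split A [assign_percentile_groups()] result for the same rows.
#' @param domain Achievement column name, e.g. `"reading"`.
#' @param covariates Optional character vector of covariate columns.
#' @return Object of class `baseline_fit` with fields `domain`,
#'   `reference_mean`, `overall_sd`, `betas`, `unstandardized`, `n`,
#'   `n_dropped`, `model`.
#' @export
fit_baseline_regression <- function(table, split, domain, covariates = NULL) {
  assert_that(domain %in% colnames(table), "domain column '%s' not found", domain)
  assert_that(length(split$group) == nrow(table),
              "split and table have different lengths")
  y <- table[[domain]]
  grp <- factor(split$group, levels = STRATUM_LEVELS, ordered = FALSE)
  dat <- data.frame(.y = y, .grp = stats::relevel(grp, ref = "TOP50"))
  if (!is.null(covariates)) {
    assert_that(all(covariates %in% colnames(table)),
                "covariates not in table: %s",
                paste(setdiff(covariates, colnames(table)), collapse = ", "))
    dat <- cbind(dat, table[covariates])
  }
  keep <- stats::complete.cases(dat)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warn_("dropping %d rows with missing values from the %s baseline fit",
          n_dropped, domain)
  dat <- dat[keep, , drop = FALSE]
  counts <- table(dat$.grp)
  empty <- names(counts)[counts == 0]
  assert_that(length(empty) == 0, "empty stratum: %s",
              paste(empty, collapse = ", "))
  overall_sd <- stats::sd(dat$.y)
  assert_that(isTRUE(overall_sd > 0),
              "overall SD of %s is zero: standardized coefficients undefined",
              domain)
  fml <- stats::as.formula(paste(".y ~ .grp",
                                 if (length(covariates)) "+" else "",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_("rank-deficient design; collinear terms: %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  b <- cf[paste0(".grp", VULNERABLE_LEVELS)]
  names(b) <- VULNERABLE_LEVELS
  structure(list(domain = domain,
                 reference_mean = mean(dat$.y[dat$.grp == "TOP50"]),
                 overall_sd = overall_sd,
                 betas = b / overall_sd,
                 unstandardized = b,
                 covariates = covariates,
                 n = nrow(dat), n_dropped = n_dropped,
                 model = fit),
            class = "baseline_fit")
}

#' Stratum-specific predicted achievement scores
#'
#' Evaluates the predicted-score formula
#' `P = M_ref - |beta| * SD` per vulnerable stratum, where `M_ref` is
#' the TOP50 mean, `beta` the outcome-standardized stratum coefficient
#' and `SD` the full-sample achievement SD. Since `beta = b / SD` this
#' reduces to `P = M_ref + b`; in the covariate-free fit each stratum's
#' predicted score is exactly its own sample mean. All children in a
#' stratum share the same predicted score.
#'
#' @param fit A `baseline_fit` or a list of them (one per domain).
#' @return Object of class `predicted_score_table`: data frame with
#'   columns `domain`, `stratum`, `predicted`.
#' @export
compute_predicted_scores <- function(fit) {
  fits <- if (inherits(fit, "baseline_fit")) list(fit) else fit
  out <- do.call(rbind, lapply(fits, function(f) {
    assert_that(inherits(f, "baseline_fit"), "expected baseline_fit objects")
    assert_that(isTRUE(f$overall_sd > 0), "overall_sd must be positive")
    data.frame(domain = f$domain,
               stratum = factor(VULNERABLE_LEVELS, levels = STRATUM_LEVELS),
               predicted = f$reference_mean + f$betas * f$overall_sd,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("predicted_score_table", "data.frame")
  out
}

#' Classify vulnerable children as resilient or ongoing-vulnerable
#'
#' A vulnerable child (any stratum below the 50th percentile at school
#' entry) is *resilient* in a domain when the actual Grade-3 score is at
#' or above the stratum's predicted score (ties count as resilient), and
#' *ongoing-vulnerable* otherwise. TOP50 children are not applicable and
#' get `NA` labels. Vulnerable children missing an achievement score are
#' excluded from that domain with a warning; exclusion counts are kept
#' in the `"excluded"` attribute.
#'
#' When the predicted table covers the two standard domains, a
#' cross-domain category is derived per child: `both`, `<domain>_only`,
#' `neither`, or `not_applicable`.
#'
#' @param table A `cohort_table`.
#' @param split Matching `vulnerability_split`.
#' @param predicted A `predicted_score_table`.
#' @return Object of class `resilience_labels`: data frame with
#'   `child_id`, `group`, `vulnerable`, one `<domain>_resilient` column
#'   per domain (integer 1/0, `NA` for TOP50 or excluded), and
#'   `category`.
#' @export
classify_resilience <- function(table, split, predicted) {
  domains <- unique(predicted$domain)
  out <- data.frame(child_id = table$child_id,
                    group = split$group,
                    vulnerable = split$vulnerable,
                    stringsAsFactors = FALSE)
  excluded <- integer(0)
  for (d in domains) {
    p <- predicted[predicted$domain == d, ]
    pmap <- stats::setNames(p$predicted, as.character(p$stratum))
    actual <- table[[d]]
    lab <- rep(NA_integer_, nrow(table))
    vul <- split$vulnerable == 1L
    miss <- vul & is.na(actual)
    if (any(miss))
      warn_("%d vulnerable children missing %s scores excluded from classification",
            sum(miss), d)
    excluded[d] <- sum(miss)
    ok <- vul & !is.na(actual)
    lab[ok] <- as.integer(actual[ok] >= pmap[as.character(split$group[ok])])
    out[[paste0(d, "_resilient")]] <- lab
  }
  if (length(domains) == 2) {
    r1 <- out[[paste0(domains[1], "_resilient")]]
    r2 <- out[[paste0(domains[2], "_resilient")]]
    cat_ <- rep(NA_character_, nrow(out))
    cat_[out$vulnerable == 0L] <- "not_applicable"
    obs <- !is.na(r1) & !is.na(r2)
    cat_[obs & r1 == 1 & r2 == 1] <- "both"
    cat_[obs & r1 == 1 & r2 == 0] <- paste0(domains[1], "_only")
    cat_[obs & r1 == 0 & r2 == 1] <- paste0(domains[2], "_only")
    cat_[obs & r1 == 0 & r2 == 0] <- "neither"
    out$category <- cat_
  }
  attr(out, "excluded") <- excluded
  attr(out, "domains") <- domains
  class(out) <- c("resilience_labels", "data.frame")
  out
}

#' Per-stratum resilient proportions (the gradient summary)
#'
#' For each vulnerable stratum and domain: how many classified children
#' were resilient vs ongoing-vulnerable. Empty strata yield `NA`
#' proportions (undefined, not zero). Proportions of resilient and
#' ongoing children sum to one within each stratum-domain cell.
#'
#' @param labels A `resilience_labels`.
#' @param split The matching `vulnerability_split` (only used for its
#'   stratum ordering; labels already carry the groups).
#' @return Data frame: `domain`, `stratum`, `n`, `n_resilient`,
#'   `prop_resilient`, `prop_ongoing`.
#' @export
gradient_summary <- function(labels, split = NULL) {
  domains <- attr(labels, "domains")
  out <- do.call(rbind, lapply(domains, function(d) {
    lab <- labels[[paste0(d, "_resilient")]]
    do.call(rbind, lapply(VULNERABLE_LEVELS, function(s) {
      in_s <- labels$group == s & !is.na(lab)
      n <- sum(in_s)
      data.frame(domain = d, stratum = s, n = n,
                 n_resilient = if (n) sum(lab[in_s]) else 0L,
                 prop_resilient = if (n) mean(lab[in_s]) else NA_real_,
                 prop_ongoing = if (n) 1 - mean(lab[in_s]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-domain resilience counts
#'
#' Tabulates the cross-domain categories and derives the per-domain and
#' at-least-one counts, with the partition identities
#' `both + reading_only = reading resilient`,
#' `both + numeracy_only = numeracy resilient`,
#' `both + reading_only + numeracy_only = at least one`.
#'
#' @param labels A `resilience_labels` with two domains.
#' @return Named list of counts and shares.
#' @export
cross_domain_summary <- function(labels) {
  domains <- attr(labels, "domains")
  assert_that(length(domains) == 2, "cross-domain summary needs two domains")
  cat_ <- labels$category
  n_both <- sum(cat_ == "both", na.rm = TRUE)
  n_only <- sapply(domains, function(d)
    sum(cat_ == paste0(d, "_only"), na.rm = TRUE))
  n_neither <- sum(cat_ == "neither", na.rm = TRUE)
  n_any <- n_both + sum(n_only)
  per_domain <- sapply(domains, function(d)
    sum(labels[[paste0(d, "_resilient")]] == 1L, na.rm = TRUE))
  n_vulnerable <- sum(labels$vulnerable)
  n_total <- nrow(labels)
  list(domains = domains,
       n_total = n_total,
       n_vulnerable = n_vulnerable,
       n_strong = n_total - n_vulnerable,
       vulnerable_share_pct = 100 * n_vulnerable / n_total,
       strong_share_pct = 100 * (n_total - n_vulnerable) / n_total,
       n_resilient = per_domain,
       resilient_pct = 100 * per_domain / n_vulnerable,
       n_both = n_both, n_only = n_only, n_neither = n_neither,
       n_at_least_one = n_any,
       at_least_one_pct = 100 * n_any / n_vulnerable,
       both_share_of_any_pct = 100 * n_both / n_any)
}
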