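#' Variance inflation factors for a predictor set
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of predictor j on the remaining predictors. Perfectly
#' collinear predictors are flagged with an infinite VIF rather than an
#' error, so the caller can report the offending columns.
#'
#' @param table Data frame holding the predictors (numeric-coded).
#' @param predictors Character vector of column names.
#' @return Data frame `predictor`, `r_squared`, `vif`, `infinite`.
#' @export
check_vif <- function(table, predictors) {
  assert_that(all(predictors %in% colnames(table)),
              "predictors not in table: %s",
              paste(setdiff(predictors, colnames(table)), collapse = ", "))
  X <- as.matrix(data.frame(lapply(table[predictors], as.numeric)))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  assert_that(nrow(X) > ncol(X) + 1, "need n > number of predictors + 1")
  out <- do.call(rbind, lapply(seq_along(predictors), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
    r2 <- min(max(r2, 0), 1)
    inf <- r2 > 1 - 1e-10
    data.frame(predictor = predictors[j], r_squared = r2,
               vif = if (inf) Inf else 1 / (1 - r2),
               infinite = inf, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Specification of the resilience path model
#'
#' Two binary resilient-membership outcomes regressed on a shared set of
#' screened explanatory variables, with socio-demographic covariates
#' added in a second (fully adjusted) stage. With binary outcomes and
#' every explanatory-to-outcome path estimated, the path estimates are
#' equivalent to outcome-wise logistic regressions.
#'
#' @param outcomes Binary outcome column names (default the two
#'   standard resilience indicators).
#' @param explanatory Explanatory variable names (those that passed the
#'   bivariate screen).
#' @param covariates Covariate names added in the adjusted stage.
#' @param link `"logit"` (default) or `"probit"`.
#' @return Object of class `path_model_spec`.
#' @export
path_model_spec <- function(outcomes = c("reading_resilient", "numeracy_resilient"),
                            explanatory,
                            covariates = c("gender", "indigenous", "lote", "sep"),
                            link = c("logit", "probit")) {
  link <- match.arg(link)
  overlap <- intersect(explanatory, covariates)
  assert_that(length(overlap) == 0,
              "explanatory and covariates overlap: %s",
              paste(overlap, collapse = ", "))
  structure(list(outcomes = outcomes, explanatory = explanatory,
                 covariates = covariates, link = link),
            class = "path_model_spec")
}

# Residual variance of the latent response: pi^2/3 for logit, 1 for probit.
latent_residual_var <- function(link) {
  if (link == "logit") pi^2 / 3 else 1
}

#' Latent-response standardized estimates from a binary-outcome fit
#'
#' Standardizes each slope as `b_j * SD(x_j) / SD(y*)`, where the latent
#' response variance is `Var(linear predictor) + pi^2/3` for the logit
#' link (`+ 1` for probit). Binary predictors are standardized with
#' their sample SD like any other column. Standard errors are scaled by
#' the same factor.
#'
#' @param fit A fitted binomial `glm`.
#' @return Data frame `term`, `estimate`, `se`, `std_estimate`,
#'   `std_se`, plus attribute `"sd_ystar"`.
#' @export
standardize_estimates <- function(fit) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  mm <- stats::model.matrix(fit)
  slopes <- setdiff(colnames(mm), "(Intercept)")
  sds <- apply(mm[, slopes, drop = FALSE], 2, stats::sd)
  zero <- slopes[sds == 0]
  assert_that(length(zero) == 0, "zero-variance predictor(s): %s",
              paste(zero, collapse = ", "))
  eta <- as.vector(mm %*% cf)
  link <- fit$family$link
  sd_ystar <- sqrt(stats::var(eta) + latent_residual_var(link))
  out <- data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
                    std_estimate = NA_real_, std_se = NA_real_,
                    stringsAsFactors = FALSE)
  for (s in slopes) {
    i <- out$term == s
    out$std_estimate[i] <- cf[s] * sds[s] / sd_ystar
    out$std_se[i] <- se[s] * sds[s] / sd_ystar
  }
  attr(out, "sd_ystar") <- sd_ystar
  out
}

#' McKelvey-Zavoina pseudo R-squared
#'
#' Variance of the fitted linear predictor over the latent-response
#' variance: `Var(eta) / (Var(eta) + pi^2/3)` for logit (`+ 1` for
#' probit). Zero for the null model; interpretable as variance explained
#' on the latent scale, matching the latent-response standardization of
#' the estimates.
#'
#' @param fit A fitted binomial `glm`.
#' @return Numeric scalar in \[0, 1\].
#' @export
pseudo_r2 <- function(fit) {
  eta <- as.vector(stats::model.matrix(fit) %*% stats::coef(fit))
  v <- stats::var(eta)
  v / (v + latent_residual_var(fit$family$link))
}

fit_one_glm <- function(data, outcome, predictors, link) {
  y <- data[[outcome]]
  assert_that(!anyNA(y), "outcome '%s' has missing values", outcome)
  assert_that(length(unique(y)) == 2,
              "outcome '%s' needs both classes present", outcome)
  dat <- data.frame(.y = as.integer(y == max(y)),
                    data.frame(lapply(data[predictors], as.numeric)))
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(link = link)),
    warning = function(w) {
      # both symptoms of separation, which the coefficient check turns
      # into an informative error below
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)[-1]
  if (!fit$converged || any(abs(cf) > 15))
    stop_("separation suspected for outcome '%s' (predictor '%s')",
          outcome, names(cf)[which.max(abs(cf))])
  fit
}

#' Fit the pooled two-stage resilience path model
#'
#' For every imputed dataset and outcome, fits a binary regression of
#' resilient group membership on the explanatory variables (unadjusted
#' stage) and on explanatory variables plus covariates (fully adjusted
#' stage); both outcomes share the predictor set, the saturated path
#' structure. Raw and latent-response standardized coefficients are
#' pooled across datasets by Rubin's rules with Barnard-Rubin degrees of
#' freedom; the McKelvey-Zavoina pseudo R-squared is averaged. A VIF
#' screen over the adjusted predictor set runs first.
#'
#' @param stack An `imputed_stack` whose tables contain the outcome and
#'   predictor columns.
#' @param spec A [path_model_spec()].
#' @param vif_threshold Maximum tolerated VIF (default 2).
#' @param vif_action `"error"` (default) or `"warn"` when the threshold
#'   is exceeded.
#' @return Object of class `path_model_fit`: list with `estimates` (data
#'   frame: `outcome`, `stage`, `term`, pooled raw and standardized
#'   columns), `r2` (per outcome/stage), `vif`, `n`, `spec`.
#' @export
fit_path_model <- function(stack, spec, vif_threshold = 2,
                           vif_action = c("error", "warn")) {
  vif_action <- match.arg(vif_action)
  assert_that(inherits(stack, "imputed_stack"), "stack must be an imputed_stack")
  assert_that(inherits(spec, "path_model_spec"), "spec must be a path_model_spec")
  tables <- stack$imputations
  m <- length(tables)
  adj <- c(spec$explanatory, spec$covariates)

  vif_tab <- do.call(rbind, lapply(tables, check_vif, predictors = adj))
  vif_max <- stats::aggregate(vif ~ predictor, data = vif_tab, FUN = max)
  over <- vif_max$predictor[vif_max$vif >= vif_threshold]
  if (length(over) > 0) {
    msg <- sprintf("VIF >= %.3g for predictor(s): %s",
                   vif_threshold, paste(over, collapse = ", "))
    if (vif_action == "error") stop_("%s", msg) else warn_("%s", msg)
  }

  stages <- list(unadjusted = spec$explanatory, adjusted = adj)
  est_rows <- list()
  r2_rows <- list()
  for (outcome in spec$outcomes) {
    for (stage in names(stages)) {
      preds <- stages[[stage]]
      raw_est <- list(); raw_var <- list()
      std_est <- list(); std_var <- list()
      r2s <- numeric(m)
      dfcom <- NA_real_
      for (i in seq_len(m)) {
        fit <- fit_one_glm(tables[[i]], outcome, preds, spec$link)
        stdz <- standardize_estimates(fit)
        raw_est[[i]] <- stats::setNames(stdz$estimate, stdz$term)
        raw_var[[i]] <- stats::setNames(stdz$se^2, stdz$term)
        std_est[[i]] <- stats::setNames(stdz$std_estimate, stdz$term)
        std_var[[i]] <- stats::setNames(stdz$std_se^2, stdz$term)
        r2s[i] <- pseudo_r2(fit)
        dfcom <- fit$df.residual
      }
      raw <- pool_rubin(raw_est, raw_var, dfcom = dfcom)
      keep <- raw$term != "(Intercept)"
      std <- pool_rubin(lapply(std_est, function(x) x[names(x) != "(Intercept)"]),
                        lapply(std_var, function(x) x[names(x) != "(Intercept)"]),
                        dfcom = dfcom)
      df_out <- data.frame(outcome = outcome, stage = stage,
                           term = raw$term,
                           estimate = raw$estimate,
                           se = sqrt(raw$total_var),
                           statistic = raw$statistic,
                           df = raw$df, p = raw$p,
                           std_estimate = NA_real_, std_se = NA_real_,
                           stringsAsFactors = FALSE)
      df_out$std_estimate[keep] <- std$estimate[match(df_out$term[keep], std$term)]
      df_out$std_se[keep] <- sqrt(std$total_var)[match(df_out$term[keep], std$term)]
      est_rows[[length(est_rows) + 1L]] <- df_out
      r2_rows[[length(r2_rows) + 1L]] <-
        data.frame(outcome = outcome, stage = stage, pseudo_r2 = mean(r2s),
                   stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, est_rows)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates,
                 r2 = do.call(rbind, r2_rows),
                 vif = vif_max,
                 n = nrow(tables[[1]]), m = m, spec = spec),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("Resilience path model: %d outcomes, m = %d imputations, n = %d\n",
              length(x$spec$outcomes), x$m, x$n))
  adj <- x$estimates[x$estimates$stage == "adjusted" &
                       x$estimates$term != "(Intercept)", ]
  for (o in unique(adj$outcome)) {
    cat("\n", o, " (fully adjusted):\n", sep = "")
    sub <- adj[adj$outcome == o, c("term", "std_estimate", "p")]
    sub$std_estimate <- round(sub$std_estimate, 2)
    sub$p <- signif(sub$p, 2)
    print(sub, row.names = FALSE)
  }
  cat("\nPseudo R-squared (McKelvey-Zavoina):\n")
  print(x$r2, row.names = FALSE)
  invisible(x)
}
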