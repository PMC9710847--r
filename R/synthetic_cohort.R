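#' Generate a synthetic longitudinal cohort
#'
#' Draws a child-level table with the statistical structure the
#' resilience analysis assumes: a standard-normal latent school-entry
#' ability inducing four percentile strata; covariates drawn from a
#' single multivariate-normal engine and transformed to their measurement
#' scales (binary by thresholding, ordinal by quantile cuts); and two
#' Grade-3 achievement domains generated as
#' `intercept + stratum effect + sum(covariate effects) + Gaussian noise`,
#' clamped to the 0-1000 score scale. Covariate effects act on the latent
#' (standard-normal) covariate scale, i.e. in score points per covariate
#' SD. The domain intercept is solved so that the TOP50 stratum mean
#' matches `achievement_mean_top50` in expectation, accounting for the
#' covariate drift induced by conditioning on above-median ability.
#'
#' The output is complete; missingness is applied separately by
#' [apply_mar_missingness()]. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A data frame (`cohort_table`): `child_id`, `entry_score`,
#'   `reading`, `numeracy`, plus one column per inventory covariate. The
#'   realized generating parameters are attached as attribute
#'   `"generator"`.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  inv <- cohort_variable_inventory()
  n <- config$n_children
  set.seed(config$seed)

  Z <- rmvn_chol(n, config$covariate_correlation)
  ability <- Z[, "ability"]
  entry_score <- ability

  cov_df <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(inv))) {
    nm <- inv$name[i]
    z <- Z[, nm]
    cov_df[[nm]] <- switch(inv$type[i],
      continuous = inv$mean[i] + inv$sd[i] * z,
      binary = as.integer(z > stats::qnorm(1 - inv$prevalence[i])),
      ordinal = {
        probs <- inv$probs[[i]]
        cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
        inv$levels[[i]][findInterval(z, cuts) + 1L]
      })
  }

  # Strata from the empirical entry-score percentiles, same convention as
  # the analysis stage (at-or-below assignment, type-7 quantiles).
  split <- assign_percentile_groups(entry_score)
  grp <- split$group

  # Expected latent-covariate mean given above-median ability, used to
  # re-anchor the intercept so the TOP50 mean hits its target.
  rho <- config$covariate_correlation["ability", rownames(config$covariate_effects)]
  drift <- sqrt(2 / pi) * rho

  ach <- list()
  for (d in names(config$stratum_effects)) {
    eff <- config$covariate_effects[, d]
    se <- config$stratum_effects[[d]]
    offset <- ifelse(grp == "TOP50", 0, se[as.character(grp)])
    intercept <- config$achievement_mean_top50[[d]] - sum(eff * drift)
    y <- intercept + offset +
      as.vector(Z[, rownames(config$covariate_effects)] %*% eff) +
      stats::rnorm(n, 0, config$residual_sd[[d]])
    ach[[d]] <- clamp(y, 0, 1000)
  }

  out <- data.frame(child_id = sprintf("C%05d", seq_len(n)),
                    entry_score = entry_score,
                    stringsAsFactors = FALSE)
  for (d in names(ach)) out[[d]] <- ach[[d]]
  out <- cbind(out, cov_df)
  rownames(out) <- NULL
  attr(out, "generator") <- list(seed = config$seed,
                                 n_children = n,
                                 entry_cutpoints = split$cutpoints,
                                 latent = "standard normal entry ability")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Mask values missing-at-random
#'
#' For every variable named in `config$missing_rates` (rate > 0), the
#' missingness indicator is drawn from a logistic model in the
#' standardized MAR drivers with slopes `config$mar_slopes`; the
#' intercept is solved numerically so the expected missingness equals
#' the target rate. Missingness therefore depends only on fully observed
#' drivers (MAR by construction). `entry_score`, achievement domains and
#' `child_id` are never masked and may not be requested.
#'
#' @param table A `cohort_table`.
#' @param config The [generator_config()] that produced it (or one whose
#'   `missing_rates`/`mar_drivers`/`mar_slopes` describe the wanted
#'   mechanism).
#' @return The table with `NA`s inserted; realized rates attached as
#'   attribute `"realized_missing_rates"`.
#' @export
apply_mar_missingness <- function(table, config) {
  rates <- config$missing_rates[config$missing_rates > 0]
  if (length(rates) == 0) return(table)
  protected <- c("child_id", "entry_score", names(config$stratum_effects))
  bad <- intersect(names(rates), protected)
  assert_that(length(bad) == 0,
              "refusing to mask protected variable(s): %s",
              paste(bad, collapse = ", "))
  missing_vars <- setdiff(names(rates), colnames(table))
  assert_that(length(missing_vars) == 0,
              "missing_rates name absent column(s): %s",
              paste(missing_vars, collapse = ", "))
  drv <- config$mar_drivers
  assert_that(all(drv %in% colnames(table)), "mar_drivers absent from table")
  assert_that(!anyNA(table[drv]), "mar_drivers must be fully observed")

  D <- scale(sapply(drv, function(v) as.numeric(table[[v]])))
  lp <- as.vector(D %*% config$mar_slopes[drv])

  # Seed offset keeps masking reproducible yet decoupled from the draws
  # used to generate the cohort itself.
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  realized <- numeric(0)
  for (v in names(rates)) {
    target <- rates[[v]]
    f <- function(a) mean(stats::plogis(a + lp)) - target
    if (f(-30) > 0 || f(30) < 0)
      stop_("missingness rate %.3f unreachable for variable '%s'", target, v)
    a <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    mask <- stats::runif(nrow(table)) < stats::plogis(a + lp)
    table[[v]][mask] <- NA
    realized[v] <- mean(mask)
  }
  attr(table, "realized_missing_rates") <- realized
  table
}

#' Write / read a cohort as CSV with a JSON sidecar
#'
#' CSV is UTF-8 with a header row and empty strings for missing values.
#' The sidecar (`<path>.json`) records the seed and realized generating
#' parameters for provenance.
#'
#' @param table A `cohort_table`.
#' @param path CSV path.
#' @return `read_cohort` returns a `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  sidecar <- list(generator = attr(table, "generator"),
                  realized_missing_rates =
                    as.list(attr(table, "realized_missing_rates") %||% list()),
                  n_rows = nrow(table), columns = colnames(table))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate binary outcomes with known standardized logit effects
#'
#' Draws independent standard-normal predictors and a binary outcome
#' from a logistic (or probit) model whose latent-response standardized
#' coefficients equal `std_effects` exactly in the population: given
#' targets s with S = sum(s^2) < 1, the raw coefficients are
#' `b = s * sqrt(v * S / (1 - S) + v)` with latent residual variance
#' `v` (pi^2/3 for logit, 1 for probit), so that
#' `b / sqrt(Var(eta) + v) = s`. Used as ground truth in
#' parameter-recovery checks of the path model.
#'
#' @param n Number of rows.
#' @param std_effects Named numeric vector of target standardized
#'   effects; names become predictor columns.
#' @param outcome Name of the binary outcome column.
#' @param link `"logit"` or `"probit"`.
#' @return Data frame of predictors plus the outcome; raw coefficients
#'   attached as attribute `"raw_coefficients"`.
#' @export
simulate_binary_outcome_data <- function(n, std_effects,
                                         outcome = "y",
                                         link = c("logit", "probit")) {
  link <- match.arg(link)
  S <- sum(std_effects^2)
  assert_that(S < 1, "sum of squared standardized effects must be < 1")
  v <- if (link == "logit") pi^2 / 3 else 1
  b <- std_effects * sqrt(v * S / (1 - S) + v)
  p <- length(std_effects)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, names(std_effects)))
  eta <- as.vector(X %*% b)
  pr <- if (link == "logit") stats::plogis(eta) else stats::pnorm(eta)
  out <- as.data.frame(X)
  out[[outcome]] <- as.integer(stats::runif(n) < pr)
  attr(out, "raw_coefficients") <- b
  out
}
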