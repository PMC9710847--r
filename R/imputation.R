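#' Configuration for multiple imputation by chained equations
#'
#' @param m Number of imputed datasets (default 40).
#' @param seed Integer RNG seed; imputation is deterministic given it.
#' @param max_iterations Chained-equation sweeps per dataset (default 20).
#' @param method_map Optional named character vector mapping variables
#'   with missing values to `"pmm"` (predictive mean matching) or
#'   `"logreg"` (Bayesian logistic draw). Unmapped variables get `pmm`
#'   when they have more than two observed levels and `logreg` when
#'   binary; ordinal variables fall under `pmm`, which by construction
#'   imputes observed donor values only.
#' @param auxiliary_variables Columns used as predictors in the
#'   imputation models but not part of the analysis model (e.g. earlier
#'   waves of the same measures).
#' @param pmm_k Number of nearest donors for predictive mean matching
#'   (default 5).
#' @return Object of class `imputation_config`.
#' @export
imputation_config <- function(m = 40L, seed = 1L, max_iterations = 20L,
                              method_map = NULL,
                              auxiliary_variables = character(),
                              pmm_k = 5L) {
  assert_that(m >= 2, "m must be at least 2 for pooling")
  assert_that(pmm_k >= 1, "pmm_k must be at least 1")
  assert_that(max_iterations >= 1, "max_iterations must be at least 1")
  structure(list(m = as.integer(m), seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 method_map = method_map,
                 auxiliary_variables = auxiliary_variables,
                 pmm_k = as.integer(pmm_k)),
            class = "imputation_config")
}

# Rank-safe least squares with a Bayesian parameter draw
# (sigma^2 from the scaled inverse-chi-square, beta from its normal
# posterior). Aliased columns get zero coefficients.
bayes_lm_draw <- function(X, y) {
  qr_ <- qr(X)
  piv <- qr_$pivot[seq_len(qr_$rank)]
  Xr <- X[, piv, drop = FALSE]
  fit <- stats::lm.fit(Xr, y)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(y) - qr_$rank, 1)
  sigma2_hat <- sum(res^2) / df
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  XtX <- crossprod(Xr)
  R <- tryCatch(chol(XtX), error = function(e)
    chol(XtX + diag(1e-8 * mean(diag(XtX)), ncol(XtX))))
  beta_star <- beta_hat +
    sqrt(sigma2_star) * backsolve(R, stats::rnorm(ncol(Xr)))
  expand <- function(b) {
    out <- numeric(ncol(X))
    out[piv] <- b
    out
  }
  list(beta_hat = expand(beta_hat), beta_star = expand(beta_star))
}

# Type-1 predictive mean matching: observed predictions from beta_hat,
# missing predictions from the drawn beta_star; each missing case takes
# the observed value of one of its k nearest donors. Donor search walks
# a sorted prediction vector, so matching is O((n_obs + n_mis) log n).
pmm_match <- function(eta_obs, eta_mis, y_obs, k) {
  k <- min(k, length(y_obs))
  ord <- order(eta_obs)
  eo <- eta_obs[ord]
  yo <- y_obs[ord]
  n <- length(eo)
  pos <- findInterval(eta_mis, eo)
  picks <- stats::runif(length(eta_mis))
  vapply(seq_along(eta_mis), function(i) {
    lo <- max(1L, pos[i] - k + 1L)
    hi <- min(n, pos[i] + k)
    window <- lo:hi
    d <- abs(eo[window] - eta_mis[i])
    donors <- window[order(d)[seq_len(k)]]
    yo[donors[ceiling(picks[i] * k)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Fills missing values by iterated conditional models: variables are
#' visited in order of increasing missingness; continuous and ordinal
#' variables are imputed by predictive mean matching (type-1 matching on
#' a Bayesian coefficient draw, k nearest donors), binary variables by a
#' Bayesian logistic draw. All other model variables (including
#' auxiliaries) serve as predictors. Observed cells are never touched,
#' and the m datasets are generated from one seeded RNG stream, so the
#' whole stack is reproducible.
#'
#' @param table Data frame with missing values (`NA`).
#' @param config An [imputation_config()].
#' @param model_variables Columns to use in the imputation model;
#'   default is every column except `child_id`. Variables with missing
#'   values must be included.
#' @return Object of class `imputed_stack`: list with `imputations`
#'   (list of m completed data frames), `trace` (per dataset/sweep/
#'   variable mean and SD of the imputed values), `config`,
#'   `imputed_variables`.
#' @export
impute_chained <- function(table, config = imputation_config(),
                           model_variables = setdiff(colnames(table), "child_id")) {
  assert_that(all(model_variables %in% colnames(table)),
              "model_variables absent from table")
  na_frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  targets <- names(na_frac)[na_frac > 0]
  all_missing <- names(na_frac)[na_frac >= 1]
  assert_that(length(all_missing) == 0,
              "variable(s) 100%% missing, cannot impute: %s",
              paste(all_missing, collapse = ", "))
  bad <- setdiff(targets, model_variables)
  assert_that(length(bad) == 0,
              "variables with missing values excluded from the model: %s",
              paste(bad, collapse = ", "))

  if (length(targets) == 0) {
    stack <- replicate(config$m, table, simplify = FALSE)
    return(structure(list(imputations = stack, trace = NULL,
                          config = config, imputed_variables = character()),
                     class = "imputed_stack"))
  }

  targets <- targets[order(na_frac[targets])]
  method <- vapply(targets, function(v) {
    mm <- config$method_map
    if (!is.null(mm) && v %in% names(mm)) return(mm[[v]])
    x <- table[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2) "pmm" else "logreg"
  }, character(1))

  miss_idx <- lapply(targets, function(v) which(is.na(table[[v]])))
  names(miss_idx) <- targets
  obs_idx <- lapply(targets, function(v) which(!is.na(table[[v]])))
  names(obs_idx) <- targets

  set.seed(config$seed)
  stack <- vector("list", config$m)
  trace <- list()
  num_tab <- data.frame(lapply(table[model_variables], as.numeric))

  for (i in seq_len(config$m)) {
    cur <- num_tab
    # starting fills: random draws from the observed margin
    for (v in targets) {
      mi <- miss_idx[[v]]
      cur[[v]][mi] <- sample(cur[[v]][obs_idx[[v]]], length(mi), replace = TRUE)
    }
    for (sweep in seq_len(config$max_iterations)) {
      for (v in targets) {
        mi <- miss_idx[[v]]; oi <- obs_idx[[v]]
        preds <- setdiff(model_variables, v)
        X <- cbind(1, as.matrix(cur[preds]))
        y_obs <- num_tab[[v]][oi]
        if (method[[v]] == "pmm") {
          dr <- bayes_lm_draw(X[oi, , drop = FALSE], y_obs)
          eta_obs <- as.vector(X[oi, , drop = FALSE] %*% dr$beta_hat)
          eta_mis <- as.vector(X[mi, , drop = FALSE] %*% dr$beta_star)
          cur[[v]][mi] <- pmm_match(eta_obs, eta_mis, y_obs, config$pmm_k)
        } else {
          lv <- sort(unique(y_obs))
          assert_that(length(lv) == 2,
                      "logreg method needs a binary variable: %s", v)
          yb <- as.integer(y_obs == lv[2])
          dat <- data.frame(.y = yb, X[oi, -1, drop = FALSE])
          fit <- suppressWarnings(
            stats::glm(.y ~ ., data = dat, family = stats::binomial()))
          cf <- stats::coef(fit)
          cf[is.na(cf)] <- 0
          V <- suppressWarnings(stats::vcov(fit))
          V[is.na(V)] <- 0
          Rv <- tryCatch(chol(V), error = function(e)
            chol(V + diag(1e-8, ncol(V))))
          cf_star <- cf + as.vector(t(Rv) %*% stats::rnorm(length(cf)))
          eta <- as.vector(X[mi, , drop = FALSE] %*% cf_star)
          cur[[v]][mi] <- lv[1 + as.integer(stats::runif(length(mi)) <
                                              stats::plogis(eta))]
        }
        trace[[length(trace) + 1L]] <- data.frame(
          dataset = i, sweep = sweep, variable = v,
          imputed_mean = mean(cur[[v]][mi]),
          imputed_sd = stats::sd(cur[[v]][mi]),
          stringsAsFactors = FALSE)
      }
    }
    completed <- table
    for (v in targets) completed[[v]][miss_idx[[v]]] <- cur[[v]][miss_idx[[v]]]
    stack[[i]] <- completed
  }
  trace <- do.call(rbind, trace)

  # crude non-convergence heuristic: drift of the imputed mean over the
  # second half of the sweeps, relative to the imputed SD
  if (config$max_iterations >= 4) {
    for (v in targets) {
      tr <- trace[trace$variable == v, ]
      half <- tr[tr$sweep > config$max_iterations / 2, ]
      drift <- abs(stats::coef(stats::lm(imputed_mean ~ sweep, data = half))[2]) *
        config$max_iterations / 2
      if (is.finite(drift) && drift > stats::median(half$imputed_sd))
        warn_("imputation trace for '%s' drifts; consider more iterations", v)
    }
  }
  structure(list(imputations = stack, trace = trace, config = config,
                 imputed_variables = targets),
            class = "imputed_stack")
}

#' Write an imputed stack to disk
#'
#' m CSV files (`imp_001.csv`, ...) plus a JSON manifest recording the
#' seed, config and convergence trace.
#'
#' @param stack An `imputed_stack`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(stack$imputations)) {
    f <- file.path(dir, sprintf("imp_%03d.csv", i))
    utils::write.csv(stack$imputations[[i]], f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  manifest <- list(m = stack$config$m, seed = stack$config$seed,
                   max_iterations = stack$config$max_iterations,
                   pmm_k = stack$config$pmm_k,
                   imputed_variables = stack$imputed_variables,
                   files = basename(files),
                   trace = stack$trace)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(mf)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Pooled estimate = mean of the per-dataset estimates; total variance =
#' within + (1 + 1/m) x between; degrees of freedom by the
#' Barnard-Rubin small-sample adjustment when a complete-data df is
#' supplied, otherwise the classical large-sample formula. P-values are
#' two-sided t.
#'
#' @param estimates m x k matrix (or list of named vectors) of
#'   per-dataset point estimates.
#' @param variances m x k matrix (or list) of their squared standard
#'   errors, aligned with `estimates`.
#' @param dfcom Complete-data residual degrees of freedom (default
#'   `Inf`, reducing Barnard-Rubin to the classical df).
#' @return Data frame of class `pooled_estimates`: `term`, `estimate`,
#'   `within_var`, `between_var`, `total_var`, `df`, `statistic`, `p`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  as_mat <- function(x, what) {
    if (is.list(x)) {
      nms <- lapply(x, names)
      assert_that(all(vapply(nms, identical, logical(1), nms[[1]])),
                  "mismatched coefficient names across datasets in %s", what)
      x <- do.call(rbind, x)
    }
    as.matrix(x)
  }
  est <- as_mat(estimates, "estimates")
  var_ <- as_mat(variances, "variances")
  assert_that(all(dim(est) == dim(var_)),
              "estimates and variances have different shapes")
  m <- nrow(est)
  assert_that(m >= 2, "pooling needs m >= 2 datasets")
  qbar <- colMeans(est)
  W <- colMeans(var_)
  B <- apply(est, 2, stats::var)
  T_ <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / T_
  df_old <- ifelse(B > 0, (m - 1) / lambda^2, Inf)
  if (is.finite(dfcom)) {
    nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / nu_obs)
  } else {
    df <- df_old
  }
  statistic <- qbar / sqrt(T_)
  p <- 2 * stats::pt(-abs(statistic), df)
  out <- data.frame(term = colnames(est) %||% paste0("b", seq_along(qbar)),
                    estimate = qbar, within_var = W, between_var = B,
                    total_var = T_, df = df, statistic = statistic, p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pooled_estimates", "data.frame")
  out
}

#' @rdname write_imputed_stack
#' @details `read_imputed_stack` rebuilds the stack from a directory
#'   written by `write_imputed_stack`; the convergence trace is restored
#'   from the manifest.
#' @export
read_imputed_stack <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  tables <- lapply(file.path(dir, mf$files), function(f)
    utils::read.csv(f, na.strings = "", stringsAsFactors = FALSE))
  structure(list(imputations = tables,
                 trace = if (!is.null(mf$trace)) as.data.frame(mf$trace),
                 config = imputation_config(m = mf$m, seed = mf$seed,
                                            max_iterations = mf$max_iterations,
                                            pmm_k = mf$pmm_k),
                 imputed_variables = mf$imputed_variables),
            class = "imputed_stack")
}
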