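test_that("VIFs are near 1 for independent predictors and closed-form under correlation", {
  set.seed(50)
  n <- 10000
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- check_vif(tab, c("a", "b", "c"))
  expect_true(all(v$vif < 1.05))
  # two predictors with correlation 0.7: VIF = 1/(1-0.49) ~ 1.96
  x <- rnorm(n)
  tab2 <- data.frame(x = x, y = 0.7 * x + sqrt(1 - 0.49) * rnorm(n))
  v2 <- check_vif(tab2, c("x", "y"))
  r2 <- summary(lm(y ~ x, tab2))$r.squared  # direct R-squared oracle
  expect_equal(v2$vif[v2$predictor == "y"], 1 / (1 - r2), tolerance = 1e-9)
  expect_equal(v2$vif[v2$predictor == "y"], 1.96, tolerance = 0.08)
  if (requireNamespace("car", quietly = TRUE)) {
    tab2$z <- rnorm(n)
    cv <- car::vif(lm(z ~ x + y, tab2))
    v3 <- check_vif(tab2, c("x", "y"))
    expect_equal(unname(cv[c("x", "y")]),
                 v3$vif[match(c("x", "y"), v3$predictor)], tolerance = 1e-6)
  }
})

test_that("perfect collinearity is flagged as infinite VIF", {
  tab <- data.frame(a = rnorm(100))
  tab$b <- tab$a
  v <- check_vif(tab, c("a", "b"))
  expect_true(all(v$infinite))
  expect_true(all(is.infinite(v$vif)))
})

test_that("latent-response standardization matches its closed form", {
  set.seed(51)
  # single standard-normal predictor with raw b = 1:
  # std = 1 / sqrt(1 + pi^2/3) ~ 0.4833
  n <- 60000
  x <- rnorm(n)
  y <- as.integer(runif(n) < plogis(x))
  fit <- glm(y ~ x, family = binomial())
  stdz <- standardize_estimates(fit)
  expect_equal(stdz$std_estimate[stdz$term == "x"],
               1 / sqrt(1 + pi^2 / 3), tolerance = 0.03)
  # invariance under unit change of the predictor
  fit2 <- glm(y ~ I(x * 10), family = binomial())
  stdz2 <- standardize_estimates(fit2)
  expect_equal(stdz2$std_estimate[2], stdz$std_estimate[2], tolerance = 1e-8)
  expect_error(standardize_estimates(glm(y ~ rep(1.5, n) + x,
                                         family = binomial())),
               "zero-variance")
})

test_that("pseudo R-squared is 0 for the null model and tracks the latent variance", {
  set.seed(52)
  y <- rbinom(500, 1, 0.4)
  expect_equal(pseudo_r2(glm(y ~ 1, family = binomial())), 0)
  # generator with known standardized effects: R2 ~ sum of squared effects
  truth <- c(x1 = 0.35, x2 = 0.25)
  dat <- simulate_binary_outcome_data(20000, truth)
  fit <- glm(y ~ x1 + x2, data = dat, family = binomial())
  expect_lt(abs(pseudo_r2(fit) - sum(truth^2)), 0.02)
  # monotone in the true effect size
  r2s <- sapply(c(0.1, 0.3, 0.5), function(s) {
    d <- simulate_binary_outcome_data(20000, c(x = s))
    pseudo_r2(glm(y ~ x, data = d, family = binomial()))
  })
  expect_true(all(diff(r2s) > 0))
})

test_that("an outcome independent of all predictors gives near-zero pseudo R-squared", {
  set.seed(53)
  dat <- data.frame(matrix(rnorm(10000 * 4), ncol = 4))
  dat$y <- rbinom(10000, 1, 0.5)
  stk <- as_stack(list(dat, dat))
  spec <- path_model_spec(outcomes = "y",
                          explanatory = paste0("X", 1:4),
                          covariates = character())
  fit <- fit_path_model(stk, spec)
  expect_lt(fit$r2$pseudo_r2[1], 0.02)
})

test_that("the pooled path model recovers known standardized effects", {
  set.seed(54)
  truth <- c(x1 = 0.35, x2 = 0.25, x3 = 0, x4 = 0)
  dat <- simulate_binary_outcome_data(4000, truth)
  stk <- as_stack(list(dat, dat))
  spec <- path_model_spec(outcomes = "y", explanatory = names(truth),
                          covariates = character())
  fit <- fit_path_model(stk, spec)
  est <- fit$estimates[fit$estimates$stage == "adjusted" &
                         fit$estimates$term != "(Intercept)", ]
  expect_lt(max(abs(est$std_estimate - truth[est$term])), 0.06)
  expect_true(all(sign(est$estimate[est$term %in% c("x1", "x2")]) == 1))
  # standardized sign always matches the raw sign
  expect_true(all(sign(est$std_estimate) == sign(est$estimate)))
})

test_that("pooled estimates are invariant to imputation order", {
  set.seed(55)
  cfg <- generator_config(n_children = 600, seed = 56,
                          missing_rates = c(attentional_regulation = 0.2))
  coh <- apply_mar_missingness(generate_cohort(cfg), cfg)
  res <- classify_pipeline(coh)
  vul <- coh[res$split$vulnerable == 1, ]
  vul$reading_resilient <- res$labels$reading_resilient[res$split$vulnerable == 1]
  stk <- impute_chained(vul, imputation_config(m = 4, seed = 8,
                                               max_iterations = 3),
                        model_variables = setdiff(colnames(vul),
                                                  c("child_id",
                                                    "reading_resilient")))
  spec <- path_model_spec(outcomes = "reading_resilient",
                          explanatory = c("attentional_regulation", "vocabulary"),
                          covariates = c("gender", "sep"))
  f1 <- fit_path_model(stk, spec)
  stk2 <- stk
  stk2$imputations <- stk$imputations[c(3, 1, 4, 2)]
  f2 <- fit_path_model(stk2, spec)
  expect_equal(f1$estimates$estimate, f2$estimates$estimate, tolerance = 1e-10)
  expect_equal(f1$estimates$p, f2$estimates$p, tolerance = 1e-10)
})

test_that("separation and single-class outcomes are refused with names", {
  set.seed(57)
  dat <- data.frame(x = c(rnorm(50, -3), rnorm(50, 3)))
  dat$y <- as.integer(dat$x > 0)  # x separates y perfectly
  stk <- as_stack(list(dat, dat))
  spec <- path_model_spec(outcomes = "y", explanatory = "x",
                          covariates = character())
  expect_error(fit_path_model(stk, spec), "separation.*x")
  dat2 <- data.frame(x = rnorm(100), y = 1L)
  stk2 <- as_stack(list(dat2, dat2))
  expect_error(fit_path_model(stk2, spec), "both classes")
})

test_that("the VIF screen gates the fit at the configured threshold", {
  set.seed(58)
  n <- 500
  x <- rnorm(n)
  dat <- data.frame(x1 = x, x2 = 0.9 * x + sqrt(1 - 0.81) * rnorm(n))
  dat$y <- rbinom(n, 1, plogis(0.5 * x))
  stk <- as_stack(list(dat, dat))
  spec <- path_model_spec(outcomes = "y", explanatory = c("x1", "x2"),
                          covariates = character())
  expect_error(fit_path_model(stk, spec, vif_threshold = 2), "VIF")
  expect_warning(fit_path_model(stk, spec, vif_threshold = 2,
                                vif_action = "warn"), "VIF")
  expect_silent(fit_path_model(stk, spec, vif_threshold = 10))
})

test_that("covariates independent of everything leave explanatory estimates unchanged", {
  set.seed(59)
  truth <- c(x1 = 0.3, x2 = 0.2)
  dat <- simulate_binary_outcome_data(8000, truth)
  dat$c1 <- rnorm(8000)
  dat$c2 <- rbinom(8000, 1, 0.5)
  stk <- as_stack(list(dat, dat))
  spec <- path_model_spec(outcomes = "y", explanatory = names(truth),
                          covariates = c("c1", "c2"))
  fit <- fit_path_model(stk, spec)
  una <- fit$estimates[fit$estimates$stage == "unadjusted" &
                         fit$estimates$term %in% names(truth), ]
  adj <- fit$estimates[fit$estimates$stage == "adjusted" &
                         fit$estimates$term %in% names(truth), ]
  expect_lt(max(abs(una$std_estimate - adj$std_estimate)), 0.03)
})
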