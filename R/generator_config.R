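#' Inventory of cohort variables emulated by the generator
#'
#' One row per covariate column of the synthetic cohort: measurement type
#' (continuous, binary or ordinal), who reports it (teacher-, parent-,
#' child-reported, direct assessment or administrative linkage), and the
#' target scale. Ordinal and binary variables are produced by cutting a
#' latent standard-normal variable at quantiles, so the `mean`/`sd`
#' columns apply only to continuous variables and `levels`/`probs`
#' only to ordinal ones.
#'
#' The reporter column drives the default missingness profile: teacher
#' questionnaires have the highest non-response (up to 24%), parent
#' interview data essentially none.
#'
#' @return A data frame with columns `name`, `type`, `reporter`, `mean`,
#'   `sd`, `prevalence`, and list-columns `levels` and `probs`.
#' @export
cohort_variable_inventory <- function() {
  v <- function(name, type, reporter, mean = NA_real_, sd = NA_real_,
                prevalence = NA_real_, levels = NULL, probs = NULL) {
    data.frame(name = name, type = type, reporter = reporter,
               mean = mean, sd = sd, prevalence = prevalence,
               levels = I(list(levels)), probs = I(list(probs)),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    v("gender",                 "binary",     "parent", prevalence = 0.49),
    v("indigenous",             "binary",     "parent", prevalence = 0.04),
    v("lote",                   "binary",     "parent", prevalence = 0.08),
    v("sep",                    "continuous", "parent", 0.00, 0.75),
    v("emotional_regulation",   "continuous", "teacher", 12.5, 3.0),
    v("attentional_regulation", "continuous", "teacher", 17.8, 3.6),
    v("sleep_problems",         "ordinal",    "parent",
      levels = 1:4, probs = c(0.70, 0.18, 0.09, 0.03)),
    v("vocabulary",             "continuous", "direct", 73.5, 5.5),
    v("peer_problems",          "continuous", "teacher", 6.1, 1.8),
    v("maternal_consistency",   "continuous", "parent", 4.25, 0.80),
    v("paternal_consistency",   "continuous", "parent", 4.15, 0.85),
    v("maternal_warmth",        "continuous", "parent", 4.30, 0.50),
    v("paternal_warmth",        "continuous", "parent", 4.10, 0.55),
    v("maternal_anger",         "continuous", "parent", 1.80, 0.55),
    v("paternal_anger",         "continuous", "parent", 1.75, 0.55),
    v("remoteness",             "ordinal",    "admin",
      levels = 0:4, probs = c(0.55, 0.25, 0.12, 0.06, 0.02)),
    v("school_sector",          "binary",     "admin", prevalence = 0.69),
    v("school_size",            "continuous", "admin", 420, 180),
    v("learning_support",       "binary",     "teacher", prevalence = 0.60),
    v("teacher_work_env",       "continuous", "teacher", 4.00, 0.60),
    v("behavior_support",       "continuous", "teacher", 3.90, 0.65),
    v("teacher_education",      "ordinal",    "teacher",
      levels = 1:7, probs = c(0.05, 0.10, 0.35, 0.25, 0.15, 0.07, 0.03)),
    v("ec_training",            "binary",     "teacher", prevalence = 0.55),
    v("teacher_self_efficacy",  "continuous", "teacher", 4.45, 0.50),
    v("parent_engagement",      "continuous", "teacher", 3.20, 1.30),
    v("teacher_closeness",      "continuous", "teacher", 21.0, 3.5),
    v("child_likes_teacher",    "ordinal",    "child",
      levels = 1:3, probs = c(0.06, 0.28, 0.66)),
    v("child_likes_school",     "continuous", "child", 17.0, 2.5),
    # Earlier-wave auxiliaries: parent-reported measures taken at age 2-3,
    # carried only to strengthen the imputation model.
    v("sep_w2",                    "continuous", "parent", 0.00, 0.75),
    v("emotional_regulation_w2",   "continuous", "parent", 12.0, 3.0),
    v("attentional_regulation_w2", "continuous", "parent", 16.5, 3.5),
    v("sleep_problems_w2",         "ordinal",    "parent",
      levels = 1:4, probs = c(0.65, 0.20, 0.10, 0.05)),
    v("maternal_hostility_w2",     "continuous", "parent", 1.90, 0.60),
    v("paternal_hostility_w2",     "continuous", "parent", 1.85, 0.60)
  ))
}

# Factor loadings behind the default covariate correlation matrix.
# Factors: G general ability, R child regulation, P parenting quality,
# S school/teacher context, E socio-economic, Z sleep. A factor structure
# guarantees a positive-definite correlation matrix (row norms < 1 leave
# positive uniquenesses).
default_factor_loadings <- function() {
  vars <- c("ability", cohort_variable_inventory()$name)
  L <- matrix(0, length(vars), 6,
              dimnames = list(vars, c("G", "R", "P", "S", "E", "Z")))
  set_l <- function(var, ...) {
    vals <- c(...)
    L[var, names(vals)] <<- vals
  }
  set_l("ability", G = 0.75, E = 0.20)
  set_l("gender", R = 0.10)
  set_l("indigenous", E = -0.30)
  set_l("sep", E = 0.80)
  set_l("emotional_regulation", R = 0.60)
  set_l("attentional_regulation", G = 0.40, R = 0.55)
  set_l("sleep_problems", R = -0.20, Z = 0.50)
  set_l("vocabulary", G = 0.55, E = 0.25)
  set_l("peer_problems", G = -0.20, R = -0.35)
  set_l("maternal_consistency", P = 0.50, E = 0.15, R = 0.15)
  set_l("paternal_consistency", P = 0.45, E = 0.15, R = 0.15)
  set_l("maternal_warmth", P = 0.45)
  set_l("paternal_warmth", P = 0.40)
  set_l("maternal_anger", P = -0.50, R = -0.15)
  set_l("paternal_anger", P = -0.45, R = -0.15)
  set_l("remoteness", E = -0.30)
  set_l("school_sector", E = -0.25)
  set_l("school_size", E = 0.15)
  set_l("learning_support", S = 0.30)
  set_l("teacher_work_env", S = 0.60)
  set_l("behavior_support", S = 0.55)
  set_l("teacher_education", S = 0.30)
  set_l("ec_training", S = 0.25)
  set_l("teacher_self_efficacy", S = 0.50)
  set_l("parent_engagement", E = 0.30, P = 0.25)
  set_l("teacher_closeness", R = 0.35, S = 0.25)
  set_l("child_likes_teacher", R = 0.20, S = 0.20)
  set_l("child_likes_school", G = 0.15, R = 0.25)
  set_l("sep_w2", E = 0.75)
  set_l("emotional_regulation_w2", R = 0.50)
  set_l("attentional_regulation_w2", G = 0.30, R = 0.45)
  set_l("sleep_problems_w2", R = -0.15, Z = 0.45)
  set_l("maternal_hostility_w2", P = -0.45)
  set_l("paternal_hostility_w2", P = -0.40)
  L
}

#' Default correlation matrix over latent entry ability and covariates
#'
#' Built from a six-factor loading structure (general ability, child
#' regulation, parenting quality, school context, socio-economic
#' position, sleep), which keeps the matrix positive definite by
#' construction. The first row/column is the latent entry ability that
#' generates the school-entry score.
#'
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
default_covariate_correlation <- function() {
  L <- default_factor_loadings()
  R <- L %*% t(L)
  diag(R) <- 1
  R
}

#' Default target missingness proportions by variable
#'
#' Teacher-questionnaire variables carry the bulk of the missingness
#' (18-24%, with teacher self-efficacy at the 24% ceiling), child-report
#' and administrative linkage variables a few percent, parent-reported
#' variables none.
#'
#' @return Named numeric vector of proportions in \[0, 0.5\].
#' @export
default_missing_rates <- function() {
  c(emotional_regulation = 0.20, attentional_regulation = 0.20,
    peer_problems = 0.18, learning_support = 0.18,
    teacher_work_env = 0.22, behavior_support = 0.22,
    teacher_education = 0.20, ec_training = 0.20,
    teacher_self_efficacy = 0.24, parent_engagement = 0.18,
    teacher_closeness = 0.18,
    child_likes_teacher = 0.05, child_likes_school = 0.05,
    school_sector = 0.02, school_size = 0.02,
    vocabulary = 0.03)
}

default_covariate_effects <- function() {
  eff <- matrix(0, nrow = nrow(cohort_variable_inventory()), ncol = 2,
                dimnames = list(cohort_variable_inventory()$name,
                                c("reading", "numeracy")))
  eff["attentional_regulation", ] <- c(20, 22)
  eff["vocabulary", ] <- c(15, 13)
  eff["sleep_problems", ] <- c(0, -9)
  eff["sep", ] <- c(13, 12)
  eff["gender", ] <- c(0, -10)
  eff
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every data-generating assumption: sample size, stratum
#' achievement offsets, covariate effects on achievement, the latent
#' correlation structure, residual noise, and the missing-at-random
#' mechanism. The defaults reproduce the structure of the study cohort
#' the pipeline is designed for: n = 2118 children, a four-stratum
#' school-entry gradient on a 0-1000 achievement scale, attentional
#' regulation and receptive vocabulary as the dominant covariate effects,
#' and teacher-reported variables missing at up to 24% driven by
#' socio-economic position and gender.
#'
#' @param n_children Number of children (at least 50, so no stratum is
#'   empty).
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the config.
#' @param stratum_effects List with one named vector per domain giving
#'   the achievement offset (score points) of each vulnerable stratum
#'   relative to the TOP50 group.
#' @param covariate_effects Numeric matrix (covariate x domain) of
#'   achievement effects in score points per latent covariate SD.
#' @param covariate_correlation Correlation matrix over latent entry
#'   ability plus all covariates; unit diagonal, positive semidefinite.
#' @param residual_sd Named per-domain residual achievement SD (> 0).
#' @param achievement_mean_top50 Named per-domain target mean
#'   achievement of the TOP50 stratum.
#' @param missing_rates Named target missingness proportions in
#'   \[0, 0.5\].
#' @param mar_drivers Names of fully observed variables that drive
#'   missingness.
#' @param mar_slopes Log-odds of missingness per SD of each driver.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_children = 2118,
                             seed = 20201,
                             stratum_effects = list(
                               reading = c(V10 = -80, V10_25 = -55, V25_50 = -30),
                               numeracy = c(V10 = -75, V10_25 = -52, V25_50 = -28)),
                             covariate_effects = default_covariate_effects(),
                             covariate_correlation = default_covariate_correlation(),
                             residual_sd = c(reading = 60, numeracy = 60),
                             achievement_mean_top50 = c(reading = 480, numeracy = 455),
                             missing_rates = default_missing_rates(),
                             mar_drivers = c("sep", "gender"),
                             mar_slopes = c(sep = -0.5, gender = 0.25)) {
  cfg <- structure(list(
    n_children = as.integer(n_children), seed = as.integer(seed),
    stratum_effects = stratum_effects,
    covariate_effects = covariate_effects,
    covariate_correlation = covariate_correlation,
    residual_sd = residual_sd,
    achievement_mean_top50 = achievement_mean_top50,
    missing_rates = missing_rates,
    mar_drivers = mar_drivers, mar_slopes = mar_slopes),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants: unit-diagonal positive-semidefinite
#' correlation matrix, positive residual SDs, missing rates in
#' \[0, 0.5\], and MAR drivers restricted to fully observed variables.
#'
#' @param cfg A `generator_config`.
#' @return The config, invisibly; errors on violation.
#' @export
validate_generator_config <- function(cfg) {
  assert_that(inherits(cfg, "generator_config"), "not a generator_config")
  assert_that(cfg$n_children >= 50L,
              "n_children = %d: need at least 50 children or strata degenerate",
              cfg$n_children)
  R <- cfg$covariate_correlation
  assert_that(is.matrix(R) && nrow(R) == ncol(R), "covariate_correlation must be square")
  assert_that(max(abs(diag(R) - 1)) < 1e-8, "covariate_correlation must have unit diagonal")
  assert_that(max(abs(R - t(R))) < 1e-8, "covariate_correlation must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8,
              "covariate_correlation is not positive semidefinite (min eigenvalue %.3g)",
              min(ev))
  assert_that(all(cfg$residual_sd > 0), "residual_sd must be > 0")
  mr <- cfg$missing_rates
  assert_that(all(mr >= 0 & mr <= 0.5), "missing_rates must lie in [0, 0.5]")
  inv <- cohort_variable_inventory()
  fully_observed <- c("entry_score",
                      setdiff(inv$name, names(mr)[mr > 0]))
  bad <- setdiff(cfg$mar_drivers, fully_observed)
  assert_that(length(bad) == 0,
              "mar_drivers must be fully observed; offending: %s",
              paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read or write a generator configuration as YAML
#'
#' The YAML mirrors the `generator_config` fields; the correlation
#' matrix and effect matrix are stored as row-named lists.
#'
#' @param path File path.
#' @param cfg A `generator_config` (for writing).
#' @return `read_generator_config` returns a `generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  mat_from <- function(x) {
    m <- do.call(rbind, lapply(x, unlist))
    rownames(m) <- names(x)
    m
  }
  defaults <- generator_config()
  generator_config(
    n_children = y$n_children %||% defaults$n_children,
    seed = y$seed %||% defaults$seed,
    stratum_effects = lapply(y$stratum_effects %||% defaults$stratum_effects, unlist),
    covariate_effects = if (is.null(y$covariate_effects))
      defaults$covariate_effects else mat_from(y$covariate_effects),
    covariate_correlation = if (is.null(y$covariate_correlation))
      defaults$covariate_correlation else {
        m <- mat_from(y$covariate_correlation); colnames(m) <- rownames(m); m
      },
    residual_sd = unlist(y$residual_sd %||% defaults$residual_sd),
    achievement_mean_top50 = unlist(y$achievement_mean_top50 %||%
                                      defaults$achievement_mean_top50),
    missing_rates = unlist(y$missing_rates) %||% defaults$missing_rates,
    mar_drivers = y$mar_drivers %||% defaults$mar_drivers,
    mar_slopes = unlist(y$mar_slopes %||% defaults$mar_slopes))
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(cfg, path) {
  validate_generator_config(cfg)
  mat_to <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(out) <- rownames(m)
    out
  }
  y <- list(n_children = cfg$n_children, seed = cfg$seed,
            stratum_effects = lapply(cfg$stratum_effects, as.list),
            covariate_effects = mat_to(cfg$covariate_effects),
            covariate_correlation = mat_to(cfg$covariate_correlation),
            residual_sd = as.list(cfg$residual_sd),
            achievement_mean_top50 = as.list(cfg$achievement_mean_top50),
            missing_rates = as.list(cfg$missing_rates),
            mar_drivers = cfg$mar_drivers,
            mar_slopes = as.list(cfg$mar_slopes))
  yaml::write_yaml(y, path, precision = 12L)
  invisible(path)
}
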