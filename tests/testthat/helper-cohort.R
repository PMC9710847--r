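# Shared fixtures, all built in code.

stratum_levels <- c("V10", "V10_25", "V25_50", "TOP50")

# A config with every systematic effect switched off: no stratum offsets,
# no covariate effects, no missingness. Achievement is then pure
# intercept + noise, which many oracle checks rely on.
zero_effect_config <- function(n = 2000, seed = 1) {
  eff <- matrix(
    0, nrow = nrow(cohort_variable_inventory()), ncol = 2,
    dimnames = list(cohort_variable_inventory()$name, c("reading", "numeracy")))
  generator_config(
    n_children = n, seed = seed,
    stratum_effects = list(reading = c(V10 = 0, V10_25 = 0, V25_50 = 0),
                           numeracy = c(V10 = 0, V10_25 = 0, V25_50 = 0)),
    covariate_effects = eff,
    missing_rates = numeric())
}

# Default-structure config without missingness, at a chosen size.
complete_config <- function(n = 2000, seed = 1) {
  generator_config(n_children = n, seed = seed, missing_rates = numeric())
}

# Fabricate a resilience_labels object from cross-domain counts, written
# independently of classify_resilience so count identities can be checked
# against a known partition.
make_labels <- function(n_both, n_reading_only, n_numeracy_only, n_neither,
                        n_top50) {
  n_vul <- n_both + n_reading_only + n_numeracy_only + n_neither
  n <- n_vul + n_top50
  df <- data.frame(
    child_id = sprintf("C%05d", seq_len(n)),
    group = factor(c(rep("V25_50", n_vul), rep("TOP50", n_top50)),
                   levels = stratum_levels, ordered = TRUE),
    vulnerable = c(rep(1L, n_vul), rep(0L, n_top50)),
    reading_resilient = c(rep(1L, n_both), rep(1L, n_reading_only),
                          rep(0L, n_numeracy_only), rep(0L, n_neither),
                          rep(NA_integer_, n_top50)),
    numeracy_resilient = c(rep(1L, n_both), rep(0L, n_reading_only),
                           rep(1L, n_numeracy_only), rep(0L, n_neither),
                           rep(NA_integer_, n_top50)),
    category = c(rep("both", n_both), rep("reading_only", n_reading_only),
                 rep("numeracy_only", n_numeracy_only),
                 rep("neither", n_neither), rep("not_applicable", n_top50)),
    stringsAsFactors = FALSE)
  attr(df, "domains") <- c("reading", "numeracy")
  attr(df, "excluded") <- c(reading = 0L, numeracy = 0L)
  class(df) <- c("resilience_labels", "data.frame")
  df
}

# Wrap a list of completed data frames as an imputed_stack (e.g. identical
# copies of complete data, for model tests that do not exercise imputation).
as_stack <- function(tables, seed = 1) {
  structure(list(imputations = tables,
                 config = imputation_config(m = max(2L, length(tables)),
                                            seed = seed),
                 trace = NULL,
                 imputed_variables = character()),
            class = "imputed_stack")
}

# Explanatory (Table-2-style) variable names: everything in the inventory
# except the socio-demographic covariates and the earlier-wave auxiliaries.
explanatory_variable_names <- function() {
  inv <- cohort_variable_inventory()$name
  setdiff(inv, c("gender", "indigenous", "lote", "sep",
                 grep("_w2$", inv, value = TRUE)))
}

# Full covariate-free classification pipeline on a cohort.
classify_pipeline <- function(cohort, cutpoints = NULL) {
  split <- assign_percentile_groups(cohort$entry_score, cutpoints = cutpoints)
  fits <- lapply(c("reading", "numeracy"), function(d)
    fit_baseline_regression(cohort, split, d))
  predicted <- compute_predicted_scores(fits)
  labels <- classify_resilience(cohort, split, predicted)
  list(split = split, fits = fits, predicted = predicted, labels = labels)
}
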