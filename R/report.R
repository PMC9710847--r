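#' Run provenance manifest
#'
#' Records everything needed to reproduce a pipeline run: an MD5 hash of
#' the serialized configuration, the seeds used, the package version,
#' digests of input files and a timestamp. Every report references the
#' manifest that produced it.
#'
#' @param config Any serializable configuration object (list).
#' @param seeds Named integer vector of the seeds used per stage.
#' @param input_files Character vector of input file paths (digested
#'   with MD5; missing files are recorded as `NA`).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = integer(),
                         input_files = character()) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  digests <- if (length(input_files))
    stats::setNames(unname(tools::md5sum(input_files)), input_files)
  else character()
  structure(list(config_hash = unname(tools::md5sum(tf)),
                 seeds = as.list(seeds),
                 package_version = as.character(utils::packageVersion("resilgap")),
                 input_digests = as.list(digests),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

fmt_pct <- function(x, digits) formatC(round(x, digits), format = "f", digits = digits)

#' Assemble the pipeline's result surfaces into one report
#'
#' Collects the analysis outputs into machine-readable tables:
#' resilience counts and rates per domain, the cross-domain partition,
#' the per-stratum gradient, stratum predicted scores, the
#' socio-demographic comparison of resilient vs ongoing-vulnerable
#' children, the explanatory-variable screen, benchmark flags, and the
#' pooled path estimates. All counts cross-foot (domain totals, the
#' cross-domain partition, stratum partitions); violations are an error,
#' because they indicate corrupted inputs. Percentages are reported at
#' the conventional precision: whole percent for group tables, two
#' decimals for sample shares.
#'
#' @param labels A `resilience_labels` (required).
#' @param predicted Optional `predicted_score_table`.
#' @param gradient Optional [gradient_summary()] output.
#' @param demographics Optional [screen_explanatory_variables()]-style
#'   data frame of socio-demographic comparisons.
#' @param screen Optional explanatory screen table; an empty data frame
#'   marks the section as present-but-empty.
#' @param path_fit Optional `path_model_fit`.
#' @param benchmarks Optional named benchmark vector; requires `cohort`.
#' @param cohort Optional `cohort_table` for benchmark group means.
#' @param manifest Optional `run_manifest`.
#' @param sections Optional character vector naming required sections;
#'   an error lists any whose inputs are missing.
#' @return List of class `resilience_report`.
#' @export
build_report <- function(labels, predicted = NULL, gradient = NULL,
                         demographics = NULL, screen = NULL, path_fit = NULL,
                         benchmarks = NULL, cohort = NULL, manifest = NULL,
                         sections = NULL) {
  assert_that(inherits(labels, "resilience_labels"),
              "labels must be a resilience_labels object")
  available <- c(resilience = TRUE,
                 predicted = !is.null(predicted),
                 gradient = !is.null(gradient),
                 demographics = !is.null(demographics),
                 screen = !is.null(screen),
                 path = !is.null(path_fit),
                 benchmarks = !is.null(benchmarks) && !is.null(cohort))
  if (!is.null(sections)) {
    missing <- setdiff(sections, names(available)[available])
    assert_that(length(missing) == 0,
                "missing inputs for requested section(s): %s",
                paste(missing, collapse = ", "))
  }
  cs <- cross_domain_summary(labels)
  # cross-footing identities; violations mean inconsistent label files
  for (d in cs$domains) {
    only <- cs$n_only[[d]]
    assert_that(cs$n_both + only == cs$n_resilient[[d]],
                "cross-domain counts do not cross-foot for %s", d)
  }
  assert_that(cs$n_both + sum(cs$n_only) == cs$n_at_least_one,
              "at-least-one count does not cross-foot")
  assert_that(cs$n_vulnerable + cs$n_strong == cs$n_total,
              "vulnerable/strong partition does not cross-foot")

  resilience_tab <- data.frame(
    domain = cs$domains,
    n_classified = sapply(cs$domains, function(d)
      sum(!is.na(labels[[paste0(d, "_resilient")]]))),
    n_resilient = unname(cs$n_resilient),
    resilient_pct = round(cs$resilient_pct, 2),
    resilient_pct_label = fmt_pct(cs$resilient_pct, 0),
    stringsAsFactors = FALSE)
  rownames(resilience_tab) <- NULL

  report <- list(
    sample = list(n_total = cs$n_total, n_vulnerable = cs$n_vulnerable,
                  n_strong = cs$n_strong,
                  vulnerable_share_pct = fmt_pct(cs$vulnerable_share_pct, 2),
                  strong_share_pct = fmt_pct(cs$strong_share_pct, 2)),
    resilience = resilience_tab,
    cross_domain = list(n_both = cs$n_both, n_only = as.list(cs$n_only),
                        n_neither = cs$n_neither,
                        n_at_least_one = cs$n_at_least_one,
                        at_least_one_pct = fmt_pct(cs$at_least_one_pct, 0),
                        both_share_of_any_pct = fmt_pct(cs$both_share_of_any_pct, 0)),
    gradient = gradient,
    predicted = predicted,
    demographics = demographics,
    screen = if (!is.null(screen) && nrow(screen) == 0)
      list(empty = TRUE) else screen,
    path = if (!is.null(path_fit))
      list(estimates = path_fit$estimates, r2 = path_fit$r2,
           vif = path_fit$vif, n = path_fit$n, m = path_fit$m),
    benchmarks = if (available[["benchmarks"]])
      benchmark_flags(group_achievement_means(cohort, labels), benchmarks),
    manifest = manifest)
  class(report) <- "resilience_report"
  report
}

#' Write a report as JSON plus CSV tables
#'
#' The scalar sections go to `report.json`; tabular sections are also
#' written as individual CSVs. Output is deterministic given the report
#' object (no timestamps are added beyond those in the manifest), so
#' regenerating from the same manifest is byte-identical.
#'
#' @param report A `resilience_report`.
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("resilience", "gradient", "predicted", "demographics",
                "screen", "benchmarks")) {
    x <- report[[tab]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(dir, paste0(tab, ".csv")), row.names = FALSE,
                       na = "")
  }
  if (!is.null(report$path)) {
    utils::write.csv(report$path$estimates,
                     file.path(dir, "path_estimates.csv"), row.names = FALSE)
  }
  out <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, dataframe = "columns")
  invisible(out)
}
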