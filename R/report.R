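#' Full Week-24 statistical battery on a cohort
#'
#' Produces the complete analysis report: raw Pearson correlations, the two
#' multivariable regressions (Week-24 density and Week-24 SAHL severity on
#' exposure, age, sex, diet), the exposure-category ANCOVA with adjusted
#' means and Bonferroni post-hocs, the exposure-by-sex interaction model,
#' sex-stratified exposure-density regressions, the SAHL psychometric
#' indices, and residual diagnostics of the density model.
#'
#' Sections whose statistic is undefined on the given data (for example a
#' constant exposure column) are reported as `{"error": <message>}` with a
#' warning rather than aborting; a cohort without Week-24 columns yields a
#' partial report with explicit `"skipped"` markers.
#'
#' @param cohort A cohort `data.frame` (from [simulate_cohort()] or
#'   [read_cohort_csv()]).
#' @return An object of class `analysis_report` (nested list, JSON-ready).
#' @export
analyze_cohort <- function(cohort) {
  section <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning("analysis section failed: ", conditionMessage(e), call. = FALSE)
      list(error = conditionMessage(e))
    })
  }
  has_wk24 <- all(c("density_week24", "sahl_total_week24") %in% names(cohort)) &&
    !anyNA(cohort$density_week24)
  skipped <- list(skipped = "Week-24 columns absent; baseline-only cohort")

  covs <- list(age = cohort$age, sex = cohort$sex, diet = cohort$diet)

  report <- list(
    schema_version = "1.0",
    n = nrow(cohort),
    correlations = if (!has_wk24) skipped else section(list(
      exposure_sahl_week24 = pearson_r(cohort$exposure, cohort$sahl_total_week24),
      exposure_density_week24 = pearson_r(cohort$exposure, cohort$density_week24),
      sahl_density_week24 = pearson_r(cohort$sahl_total_week24, cohort$density_week24),
      exposure_sahl_baseline = pearson_r(cohort$exposure, cohort$sahl_total_baseline)
    )),
    regression_sahl = if (!has_wk24) skipped else section(
      strip_model(fit_linear_model(cohort$sahl_total_week24,
                                   c(list(exposure = cohort$exposure), covs)))
    ),
    regression_density = if (!has_wk24) skipped else section(
      strip_model(fit_linear_model(cohort$density_week24,
                                   c(list(exposure = cohort$exposure), covs)))
    ),
    ancova = if (!has_wk24) skipped else section(
      strip_model(ancova(cohort$density_week24, cohort$exposure_category, covs))
    ),
    interaction = if (!has_wk24) skipped else section(
      strip_model(interaction_model(cohort$sahl_total_week24, cohort$exposure,
                                    cohort$sex,
                                    list(age = cohort$age, diet = cohort$diet)))
    ),
    stratified = if (!has_wk24) skipped else section({
      by_sex <- lapply(c(male = 0, female = 1), function(s) {
        idx <- cohort$sex == s
        fit <- fit_linear_model(cohort$density_week24[idx],
                                list(exposure = cohort$exposure[idx]))
        list(n = sum(idx),
             exposure_B = fit$coefficients$B[fit$coefficients$term == "exposure"],
             adj_r_squared = fit$adj_r_squared,
             sahl_week24_mean = mean(cohort$sahl_total_week24[idx]))
      })
      by_sex
    }),
    psychometrics = if (!has_wk24) skipped else section(reliability_report(cohort)),
    diagnostics = if (!has_wk24) skipped else section({
      fit <- fit_linear_model(cohort$density_week24,
                              c(list(exposure = cohort$exposure), covs))
      diag <- model_diagnostics(stats::residuals(fit$model),
                                cohort$exposure_category)
      diag$sahl_alpha_recomputed <- cronbach_alpha(
        cohort[, grep("^sahl_w\\d+$", names(cohort)), drop = FALSE]
      )
      diag
    })
  )
  class(report) <- "analysis_report"
  report
}

# Drop the lm object before serialization; keep the numeric table contents.
strip_model <- function(x) {
  x$model <- NULL
  cls <- class(x)
  x <- unclass(x)
  attr(x, "table_class") <- cls[1]
  x
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> schema", x$schema_version, "- n =", x$n, "\n")
  if (!is.null(x$correlations$exposure_sahl_week24$r)) {
    cat(sprintf("  r(exposure, SAHL wk24)    = %+.3f (p = %.3g)\n",
                x$correlations$exposure_sahl_week24$r,
                x$correlations$exposure_sahl_week24$p))
    cat(sprintf("  r(exposure, density wk24) = %+.3f (p = %.3g)\n",
                x$correlations$exposure_density_week24$r,
                x$correlations$exposure_density_week24$p))
  }
  if (!is.null(x$psychometrics$alpha_baseline)) {
    cat(sprintf("  Cronbach alpha: %.3f (baseline), %.3f (week 24); ICC(2,1) = %.3f\n",
                x$psychometrics$alpha_baseline, x$psychometrics$alpha_week24,
                x$psychometrics$icc_test_retest))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Full-precision, deterministically ordered JSON: identical cohorts yield
#' byte-identical report files.
#'
#' @param report An `analysis_report` (or any JSON-ready list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, force = TRUE)
  invisible(path)
}
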