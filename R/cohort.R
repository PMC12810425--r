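#' Initialize the baseline cohort
#'
#' Builds the agent table with all baseline columns: demographics (age
#' rounded to whole years and clipped to the young-adult bounds, 50:50 sex by
#' default, ordinal diet quality), baseline vertex follicular density from the
#' truncated normal, daily exposure from the zero-inflated gamma, a
#' standard-normal baseline latent severity, item-level baseline SAHL
#' responses and the equal-domain-weight total. Each random step consumes its
#' own named substream (demographics, density, exposure, likert_baseline) in
#' a fixed order, so the baseline table is byte-identical under the same seed
#' no matter what the structural coefficients are.
#'
#' @param config A [sim_config()].
#' @param rng An [rng_policy()]; defaults to one seeded from `config$seed`.
#' @return A `data.frame` with one row per agent and baseline columns filled.
#' @export
init_cohort <- function(config, rng = NULL) {
  validate_config(config)
  if (is.null(rng)) rng <- rng_policy(config$seed)
  n <- config$cohort_size

  demo <- with_stream(rng, "demographics", {
    age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
    age <- pmin(pmax(age, config$age_bounds[1]), config$age_bounds[2])
    sex <- stats::rbinom(n, 1L, config$p_female)
    diet <- sample(0:2, n, replace = TRUE, prob = config$diet_probs)
    list(age = as.integer(age), sex = as.integer(sex), diet = as.integer(diet))
  })

  density <- sample_trunc_normal(config$density, n, rng)
  exposure <- sample_exposure(config$exposure, n, rng)

  baseline <- with_stream(rng, "likert_baseline", {
    latent <- stats::rnorm(n)
    items <- sample_likert_items(config$likert, latent)
    list(latent = latent, items = items)
  })
  colnames(baseline$items) <- paste0("sahl_b", seq_len(ncol(baseline$items)))

  cohort <- data.frame(
    agent_id = seq_len(n),
    age = demo$age, sex = demo$sex, diet = demo$diet,
    exposure = exposure,
    exposure_category = categorize_exposure(exposure, config$category_cuts,
                                            config$exposure$cap),
    density_baseline = density
  )
  for (j in colnames(baseline$items)) cohort[[j]] <- baseline$items[, j]
  cohort$sahl_total_baseline <- sahl_total(baseline$items, config$likert)
  cohort$latent_baseline <- baseline$latent
  cohort
}

#' Run the full simulation pipeline
#'
#' `init_cohort()` then [compute_oxidative_load()] then [propagate_week24()],
#' all under one seeded [rng_policy()].
#'
#' @param config A [sim_config()].
#' @param seed Optional master-seed override; defaults to `config$seed`.
#' @return The completed cohort `data.frame`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  validate_config(config)
  rng <- rng_policy(if (is.null(seed)) config$seed else seed)
  cohort <- init_cohort(config, rng)
  cohort <- compute_oxidative_load(cohort, config$oxload, rng)
  propagate_week24(cohort, config$outcomes, config$likert, rng)
}

# Fixed on-disk column order for cohort CSVs.
cohort_columns <- function(k = 9L) {
  c("agent_id", "age", "sex", "diet", "exposure", "exposure_category",
    "density_baseline", paste0("sahl_b", seq_len(k)), "sahl_total_baseline",
    "latent_baseline", "oxload", "density_week24",
    paste0("sahl_w", seq_len(k)), "sahl_total_week24", "latent_week24")
}

#' Write a cohort to CSV
#'
#' Fixed column order; real-valued columns formatted at 6 significant digits
#' so identical seeds yield byte-identical files.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  k <- sum(grepl("^sahl_b", names(cohort)))
  cols <- intersect(cohort_columns(k), names(cohort))
  out <- cohort[, cols, drop = FALSE]
  for (j in names(out)) {
    x <- out[[j]]
    if (is.double(x)) out[[j]] <- sprintf("%.6g", x)
    if (is.factor(x)) out[[j]] <- as.character(x)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema written by [write_cohort_csv()]; an error lists any
#' missing columns. Week-24 columns may be absent (baseline-only tables are
#' allowed and produce partial analysis reports).
#'
#' @param path CSV path.
#' @return Cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_need <- c("agent_id", "age", "sex", "diet", "exposure",
                 "density_baseline", "sahl_total_baseline")
  missing <- setdiff(base_need, names(cohort))
  if (length(missing)) {
    stop("schema mismatch in '", path, "': missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if ("exposure_category" %in% names(cohort)) {
    cohort$exposure_category <- factor(cohort$exposure_category,
                                       levels = c("non", "light", "moderate", "heavy"))
  }
  cohort
}
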