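#' Week-24 outcome coefficients
#'
#' Linear propagation of oxidative load to the two Week-24 endpoints:
#' `D24 = D0 - beta_D * L + eta` (floored at 0) and a latent-severity shift
#' `+ beta_S * L + upsilon` feeding item-level SAHL regeneration. Both betas
#' are constrained non-negative: oxidative burden lowers density and raises
#' symptom severity by construction; the direction lives in the formulas.
#' Defaults are the shipped calibration output.
#'
#' @param beta_D Density loss (hairs/cm2) per unit oxidative load, >= 0.
#' @param beta_S Latent-severity gain per unit oxidative load, >= 0.
#' @param sigma_eta SD of the density noise `eta`, >= 0.
#' @param sigma_upsilon SD of the severity noise `upsilon`, >= 0.
#' @return An object of class `outcome_coeffs`.
#' @export
outcome_coeffs <- function(beta_D = 20.0452, beta_S = 0.442008, sigma_eta = 13.5651,
                           sigma_upsilon = 0.148121) {
  vals <- c(beta_D, beta_S, sigma_eta, sigma_upsilon)
  if (any(!is.finite(vals))) stop("configuration error: outcome coefficients must be finite")
  if (beta_D < 0 || beta_S < 0) stop("configuration error: betas must be >= 0")
  if (sigma_eta < 0 || sigma_upsilon < 0) stop("configuration error: noise SDs must be >= 0")
  structure(list(beta_D = beta_D, beta_S = beta_S, sigma_eta = sigma_eta,
                 sigma_upsilon = sigma_upsilon),
            class = "outcome_coeffs")
}

#' Propagate a cohort to Week 24
#'
#' Density: `D24 = D0 - beta_D * L + eta`, floored at 0 and deliberately NOT
#' re-truncated to the baseline physiologic range — densities below 150 are
#' the early-miniaturization signal of interest. Severity: each agent's
#' baseline latent is shifted by `beta_S * L + upsilon` and the Likert items
#' are regenerated from the shifted latent with the same thresholds and
#' inter-item correlation but fresh item noise; regenerating at item level is
#' what makes Week-24 internal consistency and test-retest reliability
#' well-defined quantities.
#'
#' @param cohort Cohort with `oxload` filled (see [compute_oxidative_load()]).
#' @param coeffs An [outcome_coeffs()] object.
#' @param likert The [likert_spec()] shared with the baseline instrument.
#' @param rng Optional [rng_policy()]; uses streams `"outcome_noise"` and
#'   `"likert_week24"`.
#' @return The cohort with Week-24 columns filled.
#' @export
propagate_week24 <- function(cohort, coeffs, likert, rng = NULL) {
  stopifnot(inherits(coeffs, "outcome_coeffs"), inherits(likert, "likert_spec"))
  if (!"oxload" %in% names(cohort) || anyNA(cohort$oxload)) {
    stop("state error: 'oxload' must be computed before Week-24 propagation")
  }
  n <- nrow(cohort)
  noise <- .with_rng(rng, "outcome_noise", {
    list(eta = stats::rnorm(n, 0, coeffs$sigma_eta),
         upsilon = stats::rnorm(n, 0, coeffs$sigma_upsilon))
  })
  cohort$density_week24 <- pmax(
    cohort$density_baseline - coeffs$beta_D * cohort$oxload + noise$eta, 0
  )
  cohort$latent_week24 <- cohort$latent_baseline +
    coeffs$beta_S * cohort$oxload + noise$upsilon
  items <- sample_likert_items(likert, cohort$latent_week24, rng,
                               stream = "likert_week24")
  colnames(items) <- paste0("sahl_w", seq_len(ncol(items)))
  for (j in colnames(items)) cohort[[j]] <- items[, j]
  cohort$sahl_total_week24 <- sahl_total(items, likert)
  cohort
}

#' Categorize daily exposure into use strata
#'
#' Non-user iff exactly zero; then half-open intervals `(0, light]`,
#' `(light, moderate]`, and above. The default cut-points 0.5 and 1.5 g/day
#' are chosen so all four strata are non-empty in a typical 140-agent draw
#' from the default exposure distribution; they are configurable.
#'
#' @param x Numeric exposures in `[0, 5]`.
#' @param cuts Two increasing positive cut-points `c(light_max, moderate_max)`.
#' @param cap Upper support bound (domain check only).
#' @return Factor with ordered levels `non`, `light`, `moderate`, `heavy`.
#' @export
categorize_exposure <- function(x, cuts = c(0.5, 1.5), cap = 5) {
  if (length(cuts) != 2L || any(diff(cuts) <= 0) || any(cuts <= 0)) {
    stop("configuration error: 'cuts' must be two increasing positive values")
  }
  if (any(x < 0 | x > cap)) {
    stop("domain error: exposure outside [0, ", cap, "]")
  }
  lev <- c("non", "light", "moderate", "heavy")
  out <- ifelse(x == 0, "non",
         ifelse(x <= cuts[1], "light",
         ifelse(x <= cuts[2], "moderate", "heavy")))
  factor(out, levels = lev)
}
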