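#' Oxidative-load coefficients
#'
#' Coefficients of the latent oxidative-load index
#' `L_i = alpha_x * X_i + alpha_sex * sex_i + alpha_diet * (2 - diet_i) + eps_i`
#' with `eps_i ~ N(0, sigma_eps)`. Higher exposure, female sex and poorer diet
#' each increase the index. The error term is additive: the index is a
#' weighted linear combination of the three oxidative-stress modifiers plus
#' mean-zero normal noise. The default values are the shipped calibration
#' output (see [calibrate_simulation()]); no published coefficient magnitudes
#' exist, only the summary statistics they were tuned to reproduce.
#' `alpha_x` is fixed at 1 by convention (the index is
#' unitless and its scale is absorbed by the outcome coefficients), which pins
#' the otherwise scale-confounded parameterization.
#'
#' @param alpha_x Exposure weight, per g/day.
#' @param alpha_sex Female-sex weight.
#' @param alpha_diet Weight per point of diet deficit `(2 - diet)`.
#' @param sigma_eps SD of the additive normal error, >= 0.
#' @return An object of class `oxload_coeffs`.
#' @export
oxload_coeffs <- function(alpha_x = 1, alpha_sex = 1.07513, alpha_diet = 0.147836,
                          sigma_eps = 1.45008) {
  vals <- c(alpha_x, alpha_sex, alpha_diet, sigma_eps)
  if (any(!is.finite(vals))) stop("configuration error: oxload coefficients must be finite")
  if (sigma_eps < 0) stop("configuration error: 'sigma_eps' must be >= 0")
  structure(list(alpha_x = alpha_x, alpha_sex = alpha_sex,
                 alpha_diet = alpha_diet, sigma_eps = sigma_eps),
            class = "oxload_coeffs")
}

#' Compute the latent oxidative load of every agent
#'
#' Fills the `oxload` column of a baseline cohort:
#' `L = alpha_x * exposure + alpha_sex * sex + alpha_diet * (2 - diet) + eps`,
#' `eps ~ N(0, sigma_eps)` drawn from the `"oxload_noise"` stream.
#'
#' @param cohort A cohort data frame from [init_cohort()].
#' @param coeffs An [oxload_coeffs()] object.
#' @param rng Optional [rng_policy()].
#' @return The cohort with `oxload` filled.
#' @export
compute_oxidative_load <- function(cohort, coeffs, rng = NULL) {
  stopifnot(inherits(coeffs, "oxload_coeffs"))
  need <- c("exposure", "sex", "diet")
  if (!all(need %in% names(cohort))) {
    stop("state error: baseline columns missing: ",
         paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  n <- nrow(cohort)
  eps <- .with_rng(rng, "oxload_noise", stats::rnorm(n, 0, coeffs$sigma_eps))
  cohort$oxload <- coeffs$alpha_x * cohort$exposure +
    coeffs$alpha_sex * cohort$sex +
    coeffs$alpha_diet * (2 - cohort$diet) + eps
  cohort
}
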