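#' Calibration targets
#'
#' The printed summary statistics the free structural coefficients are tuned
#' to reproduce, with per-target tolerances and weights. Correlation,
#' reliability and adjusted-R2 targets carry a 0.03 tolerance, exposure
#' moments 0.02, sex-specific SAHL means 0.3; the test-retest ICC is a
#' one-sided floor (values above it are not penalized). The tolerances scale
#' the loss, `sum(w * ((achieved - target) / tol)^2)`, so each target is
#' penalized in units of its own acceptable error.
#'
#' @param values Named numeric overrides of target values.
#' @param tolerances Named numeric overrides of tolerances (> 0).
#' @param weights Named numeric overrides of weights.
#' @return An object of class `calibration_targets`.
#' @export
calibration_targets <- function(values = NULL, tolerances = NULL, weights = NULL) {
  v <- c(r_exposure_sahl = 0.31, r_exposure_density = -0.38,
         r_sahl_density_convergent = 0.47,
         alpha_baseline = 0.51, alpha_week24 = 0.54, icc_min = 0.52,
         exposure_mean = 1.07, exposure_sd = 0.84,
         sahl_mean_female_wk24 = 7.4, sahl_mean_male_wk24 = 6.1,
         adj_r2_density = 0.21, adj_r2_sahl = 0.19)
  tol <- c(r_exposure_sahl = 0.03, r_exposure_density = 0.03,
           r_sahl_density_convergent = 0.03,
           alpha_baseline = 0.03, alpha_week24 = 0.03, icc_min = 0.03,
           exposure_mean = 0.02, exposure_sd = 0.02,
           sahl_mean_female_wk24 = 0.3, sahl_mean_male_wk24 = 0.3,
           adj_r2_density = 0.03, adj_r2_sahl = 0.03)
  w <- stats::setNames(rep(1, length(v)), names(v))
  for (nm in names(values)) v[nm] <- values[[nm]]
  for (nm in names(tolerances)) tol[nm] <- tolerances[[nm]]
  for (nm in names(weights)) w[nm] <- weights[[nm]]
  if (any(!is.finite(tol)) || any(tol <= 0)) {
    stop("configuration error: tolerances must be > 0")
  }
  if (any(abs(v[grep("^(r_|alpha_|icc)", names(v))]) >= 1)) {
    stop("configuration error: correlation-type targets must lie in (-1, 1)")
  }
  structure(list(values = v, tolerances = tol, weights = w,
                 one_sided = "icc_min"),
            class = "calibration_targets")
}

#' Measure the calibration summary vector of a configuration
#'
#' Runs the full init -> oxidative load -> Week-24 pipeline on one large
#' cohort and computes every calibration target statistic with the same
#' estimators the analysis module uses: Pearson correlations, Cronbach alpha,
#' ICC(2,1), OLS adjusted R2 on the exposure + age + sex + diet models, and
#' the sex-specific Week-24 SAHL means. The convergent severity-density
#' statistic is reported as a magnitude (the generating model makes it
#' negative; the target tables print its size).
#'
#' @param config A [sim_config()].
#' @param n_eval Evaluation cohort size (>= 1000 for standard-error control).
#' @param seed Master seed for the evaluation cohort.
#' @return Named numeric vector over all calibration target fields.
#' @export
summarize_simulation <- function(config, n_eval = 20000, seed = config$seed) {
  validate_config(config)
  if (n_eval < 1000) stop("'n_eval' must be >= 1000 for standard-error control")
  cfg <- config
  cfg$cohort_size <- as.integer(n_eval)
  cohort <- simulate_cohort(cfg, seed = seed)
  if (stats::sd(cohort$exposure) == 0) {
    stop("calibration error: degenerate config (zero-variance exposure)")
  }
  rel <- reliability_report(cohort)
  covs <- list(exposure = cohort$exposure, age = cohort$age,
               sex = cohort$sex, diet = cohort$diet)
  fit_d <- fit_linear_model(cohort$density_week24, covs)
  fit_s <- fit_linear_model(cohort$sahl_total_week24, covs)
  c(
    r_exposure_sahl = pearson_r(cohort$exposure, cohort$sahl_total_week24)$r,
    r_exposure_density = pearson_r(cohort$exposure, cohort$density_week24)$r,
    r_sahl_density_convergent = abs(rel$convergent_r),
    alpha_baseline = rel$alpha_baseline,
    alpha_week24 = rel$alpha_week24,
    icc_min = rel$icc_test_retest,
    exposure_mean = mean(cohort$exposure),
    exposure_sd = stats::sd(cohort$exposure),
    sahl_mean_female_wk24 = mean(cohort$sahl_total_week24[cohort$sex == 1]),
    sahl_mean_male_wk24 = mean(cohort$sahl_total_week24[cohort$sex == 0]),
    adj_r2_density = fit_d$adj_r_squared,
    adj_r2_sahl = fit_s$adj_r_squared
  )
}

# Free calibration parameters and their transforms. alpha_x stays fixed at 1
# to pin the scale of the otherwise alpha/beta-confounded parameterization.
.calib_params <- data.frame(
  name = c("alpha_sex", "alpha_diet", "sigma_eps", "beta_D", "beta_S",
           "sigma_eta", "sigma_upsilon", "item_corr", "thr_shift",
           "p_nonuser", "shape", "scale"),
  transform = c("log", "log", "log", "log", "log", "log", "log", "logit",
                "identity", "logit", "log", "log"),
  stringsAsFactors = FALSE
)

.to_unconstrained <- function(value, transform) {
  switch(transform,
         log = log(pmax(value, 1e-8)),
         logit = stats::qlogis(pmin(pmax(value, 1e-8), 1 - 1e-8)),
         identity = value)
}

.from_unconstrained <- function(theta, transform) {
  switch(transform, log = exp(theta), logit = stats::plogis(theta),
         identity = theta)
}

# Extract the free-parameter values of a config (thr_shift measured relative
# to `base`, the thresholds of the initial config).
.get_param <- function(config, name, base_thresholds) {
  switch(name,
    alpha_sex = config$oxload$alpha_sex,
    alpha_diet = config$oxload$alpha_diet,
    sigma_eps = config$oxload$sigma_eps,
    beta_D = config$outcomes$beta_D,
    beta_S = config$outcomes$beta_S,
    sigma_eta = config$outcomes$sigma_eta,
    sigma_upsilon = config$outcomes$sigma_upsilon,
    item_corr = config$likert$item_corr,
    thr_shift = config$likert$thresholds[1] - base_thresholds[1],
    p_nonuser = config$exposure$p_nonuser,
    shape = config$exposure$shape,
    scale = config$exposure$scale,
    stop("unknown calibration parameter: ", name)
  )
}

.set_param <- function(config, name, value, base_thresholds) {
  switch(name,
    alpha_sex = config$oxload$alpha_sex <- value,
    alpha_diet = config$oxload$alpha_diet <- value,
    sigma_eps = config$oxload$sigma_eps <- value,
    beta_D = config$outcomes$beta_D <- value,
    beta_S = config$outcomes$beta_S <- value,
    sigma_eta = config$outcomes$sigma_eta <- value,
    sigma_upsilon = config$outcomes$sigma_upsilon <- value,
    item_corr = config$likert$item_corr <- value,
    thr_shift = config$likert$thresholds <- base_thresholds + value,
    p_nonuser = config$exposure$p_nonuser <- value,
    shape = config$exposure$shape <- value,
    scale = config$exposure$scale <- value
  )
  config
}

#' Weighted calibration loss of a summary vector
#'
#' `sum(w * ((achieved - target) / tolerance)^2)` over all targets; one-sided
#' targets (the ICC floor) contribute only when the achieved value falls
#' below the target.
#'
#' @param achieved Named summary vector from [summarize_simulation()].
#' @param targets A [calibration_targets()] object.
#' @return Scalar loss.
#' @export
calibration_loss <- function(achieved, targets) {
  stopifnot(inherits(targets, "calibration_targets"))
  if (any(!is.finite(achieved))) {
    stop("non-finite achieved statistic: ",
         paste(names(achieved)[!is.finite(achieved)], collapse = ", "))
  }
  resid <- (achieved[names(targets$values)] - targets$values) / targets$tolerances
  for (nm in targets$one_sided) {
    if (achieved[[nm]] >= targets$values[[nm]]) resid[nm] <- 0
  }
  sum(targets$weights * resid^2)
}

#' Calibrate free coefficients to the target summary statistics
#'
#' Derivative-free Nelder-Mead minimization of [calibration_loss()] over
#' log/logit-transformed free parameters, with common random numbers: every
#' candidate configuration is evaluated on the same master seed, so the loss
#' surface is deterministic and the optimization is reproducible. Calibration
#' runs at large `n_eval` (population level) rather than at the 140-agent
#' study size, whose sampling error (about 0.08 on a correlation) would
#' swamp the targets.
#'
#' @param initial Starting [sim_config()].
#' @param targets A [calibration_targets()] object.
#' @param budget Maximum number of loss evaluations (>= 1).
#' @param n_eval Evaluation cohort size per loss evaluation.
#' @param seed Common-random-number master seed.
#' @param free Character vector of parameters to optimize; defaults to all
#'   twelve free parameters (`alpha_x` is always fixed at 1).
#' @param trace If `TRUE`, logs the loss trajectory to stderr.
#' @return An object of class `calibration_result`: `config` (fitted),
#'   `achieved`, `loss`, `initial_loss`, `n_eval`, `seed`, `evaluations`,
#'   `converged`.
#' @export
calibrate_simulation <- function(initial, targets = calibration_targets(),
                                 budget = 2000, n_eval = 20000,
                                 seed = initial$seed,
                                 free = .calib_params$name, trace = FALSE) {
  validate_config(initial)
  stopifnot(inherits(targets, "calibration_targets"))
  if (budget < 1) stop("'budget' must be >= 1")
  bad <- setdiff(free, .calib_params$name)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  params <- .calib_params[.calib_params$name %in% free, , drop = FALSE]
  base_thr <- initial$likert$thresholds

  apply_theta <- function(theta) {
    cfg <- initial
    for (i in seq_len(nrow(params))) {
      cfg <- .set_param(cfg, params$name[i],
                        .from_unconstrained(theta[i], params$transform[i]),
                        base_thr)
    }
    cfg
  }
  evals <- 0L
  loss_fn <- function(theta) {
    evals <<- evals + 1L
    cfg <- apply_theta(theta)
    ach <- tryCatch(summarize_simulation(cfg, n_eval, seed = seed),
                    error = function(e) NULL)
    if (is.null(ach) || any(!is.finite(ach))) return(1e10)
    loss <- calibration_loss(ach, targets)
    if (trace) message(sprintf("calibration eval %d: loss = %.4f", evals, loss))
    loss
  }

  theta0 <- vapply(seq_len(nrow(params)), function(i) {
    .to_unconstrained(.get_param(initial, params$name[i], base_thr),
                      params$transform[i])
  }, numeric(1))
  loss0 <- loss_fn(theta0)

  if (budget <= 1 || length(theta0) == 0L) {
    best_theta <- theta0
    best_loss <- loss0
    converged <- TRUE
  } else if (length(theta0) == 1L) {
    opt <- stats::optim(theta0, loss_fn, method = "Brent",
                        lower = theta0 - 8, upper = theta0 + 8)
    best_theta <- opt$par; best_loss <- opt$value
    converged <- opt$convergence == 0
  } else {
    opt <- stats::optim(theta0, loss_fn, method = "Nelder-Mead",
                        control = list(maxit = budget, reltol = 1e-6))
    best_theta <- opt$par; best_loss <- opt$value
    converged <- opt$convergence == 0
  }
  if (best_loss > loss0) {  # never return worse than the starting point
    best_theta <- theta0; best_loss <- loss0
  }
  fitted <- apply_theta(best_theta)
  achieved <- summarize_simulation(fitted, n_eval, seed = seed)
  structure(list(config = fitted, achieved = achieved, loss = best_loss,
                 initial_loss = loss0, n_eval = n_eval, seed = seed,
                 evaluations = evals, converged = converged,
                 targets = targets),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> loss %.3f (from %.3f), %d evaluations, n_eval = %d\n",
              x$loss, x$initial_loss, x$evaluations, x$n_eval))
  tab <- data.frame(target = names(x$targets$values),
                    target_value = unname(x$targets$values),
                    achieved = unname(x$achieved[names(x$targets$values)]))
  tab$achieved <- round(tab$achieved, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
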