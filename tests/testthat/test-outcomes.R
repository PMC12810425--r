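loaded_cohort <- function(n = 500, seed = 5, cfg = default_config(cohort_size = n)) {
  rng <- rng_policy(seed)
  co <- init_cohort(cfg, rng)
  compute_oxidative_load(co, cfg$oxload, rng)
}

test_that("null propagation leaves density and latent severity unchanged", {
  cfg <- default_config(cohort_size = 200)
  co <- loaded_cohort(200, cfg = cfg)
  out <- propagate_week24(co, outcome_coeffs(0, 0, 0, 0), cfg$likert,
                          rng_policy(9))
  expect_equal(out$density_week24, out$density_baseline)
  expect_equal(out$latent_week24, out$latent_baseline)
})

test_that("deterministic propagation shifts density by exactly beta_D * L", {
  cfg <- default_config(cohort_size = 100)
  co <- loaded_cohort(100, cfg = cfg)
  out <- propagate_week24(co, outcome_coeffs(beta_D = 10, beta_S = 0,
                                             sigma_eta = 0, sigma_upsilon = 0),
                          cfg$likert, rng_policy(2))
  expect_equal(out$density_week24,
               pmax(out$density_baseline - 10 * out$oxload, 0))
})

test_that("week-24 items regenerate near-identically when item noise vanishes", {
  cfg <- default_config(cohort_size = 2000,
                        likert = likert_spec(item_corr = 0.99999))
  co <- loaded_cohort(2000, cfg = cfg)
  out <- propagate_week24(co, outcome_coeffs(0, 0, 0, 0), cfg$likert,
                          rng_policy(3))
  b <- as.matrix(out[, paste0("sahl_b", 1:9)])
  w <- as.matrix(out[, paste0("sahl_w", 1:9)])
  expect_gt(mean(b == w), 0.97)
})

test_that("exposure categories use the stated half-open boundaries", {
  x <- c(0, 0.25, 0.5, 0.51, 1.5, 1.51, 5.0)
  expect_identical(as.character(categorize_exposure(x)),
                   c("non", "light", "light", "moderate", "moderate",
                     "heavy", "heavy"))
  expect_error(categorize_exposure(-0.1), "domain error")
  expect_error(categorize_exposure(5.1), "domain error")
})

test_that("mean week-24 density decreases monotonically across exposure strata", {
  co <- simulate_cohort(default_config(cohort_size = 1e5), seed = 12)
  m <- tapply(co$density_week24, co$exposure_category, mean)
  expect_true(all(diff(m) < 0))
})

test_that("null outcome model recovers zero exposure-outcome correlations", {
  cfg <- default_config(cohort_size = 1e5,
                        outcomes = outcome_coeffs(beta_D = 0, beta_S = 0,
                                                  sigma_eta = 6,
                                                  sigma_upsilon = 0.3))
  co <- simulate_cohort(cfg, seed = 8)
  expect_lt(abs(cor(co$exposure, co$density_week24)), 0.03)
  expect_lt(abs(cor(co$exposure, co$sahl_total_week24)), 0.03)
})

test_that("|r(exposure, density)| increases with beta_D under a fixed seed", {
  rs <- vapply(c(2, 8, 20), function(bd) {
    cfg <- default_config(cohort_size = 5000,
                          outcomes = outcome_coeffs(beta_D = bd, beta_S = 0.4,
                                                    sigma_eta = 6,
                                                    sigma_upsilon = 0.3))
    co <- simulate_cohort(cfg, seed = 123)
    abs(cor(co$exposure, co$density_week24))
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("week-24 density is floored at zero, not re-truncated to baseline range", {
  cfg <- default_config(cohort_size = 2000,
                        outcomes = outcome_coeffs(beta_D = 60, beta_S = 0.4,
                                                  sigma_eta = 30,
                                                  sigma_upsilon = 0.3))
  co <- simulate_cohort(cfg, seed = 6)
  expect_true(all(co$density_week24 >= 0))
  expect_true(any(co$density_week24 < 150))  # miniaturization below baseline range
})

test_that("propagation without oxidative load raises a state error", {
  co <- init_cohort(default_config(cohort_size = 10), rng_policy(1))
  expect_error(propagate_week24(co, outcome_coeffs(), likert_spec()),
               "state error")
})
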