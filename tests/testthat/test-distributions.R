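test_that("truncated-normal sampler respects bounds and matches closed-form moments", {
  spec <- trunc_norm_spec(185, 28, 150, 220)
  rng <- rng_policy(11)
  x <- sample_trunc_normal(spec, 140, rng)
  expect_true(all(x >= 150 & x <= 220))

  x <- sample_trunc_normal(spec, 1e5, rng_policy(7))
  o <- trunc_normal_moments(185, 28, 150, 220)
  se <- o$sd / sqrt(1e5)
  expect_lt(abs(mean(x) - o$mean), max(0.5, 3 * se))
  expect_lt(abs(sd(x) - o$sd), 3 * o$sd / sqrt(2 * 1e5) + 0.2)
})

test_that("truncated-normal sampler handles a degenerate SD", {
  spec <- trunc_norm_spec(185, 1e-9, 150, 220)
  x <- sample_trunc_normal(spec, 10, rng_policy(1))
  expect_equal(x, rep(185, 10), tolerance = 1e-6)
})

test_that("samplers are deterministic given an identical seed and spec", {
  spec <- trunc_norm_spec()
  espec <- exposure_spec()
  lspec <- likert_spec()
  a <- sample_trunc_normal(spec, 500, rng_policy(42))
  b <- sample_trunc_normal(spec, 500, rng_policy(42))
  expect_identical(a, b)
  a <- sample_exposure(espec, 500, rng_policy(42))
  b <- sample_exposure(espec, 500, rng_policy(42))
  expect_identical(a, b)  # includes the truncation-resampling branch
  la <- rnorm(200)
  a <- sample_likert_items(lspec, la, rng_policy(42))
  b <- sample_likert_items(lspec, la, rng_policy(42))
  expect_identical(a, b)
})

test_that("exposure mixture hits its zero mass, cap, and calibrated moments", {
  spec <- exposure_spec()
  x <- sample_exposure(spec, 1e5, rng_policy(3))
  expect_true(all(x >= 0 & x <= 5))
  expect_lt(abs(mean(x == 0) - spec$p_nonuser), 0.01)
  expect_lt(abs(mean(x) - 1.07), 0.02)
  expect_lt(abs(sd(x) - 0.84), 0.02)

  near_all_zero <- exposure_spec(p_nonuser = 1 - 1e-12)
  expect_true(all(sample_exposure(near_all_zero, 100, rng_policy(1)) == 0))

  expect_error(exposure_spec(cap = 0), "cap")
})

test_that("samplers respect their supports across sizes (property)", {
  for (n in c(1, 17, 1000, 1e5)) {
    rng <- rng_policy(n)
    expect_true(all(sample_trunc_normal(trunc_norm_spec(), n, rng) >= 150))
    x <- sample_exposure(exposure_spec(), n, rng)
    expect_true(all(x >= 0 & x <= 5))
    items <- sample_likert_items(likert_spec(), rnorm(n), rng)
    expect_true(all(items %in% 1:5))
    expect_identical(dim(items), c(as.integer(n), 9L))
  }
})

test_that("likert items follow the equicorrelation model at its extremes", {
  latent <- with_stream(rng_policy(5), "likert_baseline", rnorm(1e5))
  ind <- sample_likert_items(likert_spec(item_corr = 0), latent, rng_policy(6))
  cors <- cor(ind)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.03)

  dup <- sample_likert_items(likert_spec(item_corr = 0.99999), latent[1:2000],
                             rng_policy(6))
  same <- apply(dup, 1, function(r) all(r == r[1]))
  expect_gt(mean(same), 0.97)
})

test_that("continuous equicorrelated items reproduce the closed-form alpha", {
  # alpha = k * rho / (1 + (k - 1) * rho) = 9 * 0.107 / (1 + 8 * 0.107) = 0.519
  spec <- likert_spec(item_corr = 0.107)
  latent <- with_stream(rng_policy(8), "likert_baseline", rnorm(1e5))
  u <- sample_likert_latents(spec, latent, rng_policy(9))
  expect_lt(abs(cronbach_alpha(u) - 9 * 0.107 / (1 + 8 * 0.107)), 0.02)
})

test_that("spec constructors validate their invariants", {
  expect_error(trunc_norm_spec(sd = -1), "sd")
  expect_error(trunc_norm_spec(lower = 220, upper = 150), "lower")
  expect_error(exposure_spec(p_nonuser = 1.2), "p_nonuser")
  expect_error(likert_spec(item_corr = 1), "item_corr")
  expect_error(likert_spec(thresholds = c(0, -1, 1, 2)), "increasing")
})
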