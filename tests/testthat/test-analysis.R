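test_that("pearson_r is exact for perfect linearity and validates input", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_error(pearson_r(x, rep(3, 6)), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("pearson p-value agrees with the exhaustive permutation oracle", {
  res <- pearson_r(toy_x6, toy_y6)
  p_perm <- permutation_p_exhaustive(toy_x6, toy_y6)
  # the t-transform p and the exact permutation p agree within the
  # permutation granularity of a 6-point set (720 permutations)
  expect_lt(abs(res$p - p_perm), 2 / sqrt(720))
})

test_that("OLS coefficients match the normal-equations oracle to 1e-10", {
  fit <- fit_linear_model(toy_reg$y, toy_reg[, c("x1", "x2", "x3")])
  oracle <- ols_normal_equations(toy_reg$y, toy_reg[, c("x1", "x2", "x3")])
  expect_equal(fit$coefficients$B, unname(oracle), tolerance = 1e-10)
})

test_that("an exact linear outcome gives R2 = 1 and zero residuals", {
  y <- 2 + 3 * toy_reg$x1 - 1.5 * toy_reg$x2
  # lm warns about the (intended) perfect fit
  fit <- suppressWarnings(fit_linear_model(y, toy_reg[, c("x1", "x2")]))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit$model))), 1e-10)
})

test_that("standardized beta on a single predictor equals the Pearson r", {
  set.seed(7)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  fit <- fit_linear_model(y, list(x = x))
  expect_equal(fit$coefficients$std_beta[fit$coefficients$term == "x"],
               cor(x, y), tolerance = 1e-12)
})

test_that("regression tables satisfy their structural invariants", {
  set.seed(8)
  for (i in 1:10) {
    n <- 40
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = sample(0:1, n, TRUE))
    y <- 0.5 * X$a - 0.2 * X$c + rnorm(n)
    fit <- fit_linear_model(y, X)
    expect_lte(fit$adj_r_squared, fit$r_squared)
    tab <- fit$coefficients
    expect_true(all(tab$ci_lower <= tab$B & tab$B <= tab$ci_upper))
    expect_true(all(tab$p >= 0 & tab$p <= 1))
  }
})

test_that("rank-deficient designs raise a collinearity error", {
  expect_error(
    fit_linear_model(toy_reg$y,
                     data.frame(x1 = toy_reg$x1, dup = toy_reg$x1)),
    "collinearity"
  )
  expect_error(
    interaction_model(toy_reg$y, toy_reg$x1, rep(1, 10)),
    "collinearity"
  )
})

test_that("ANCOVA F equals the brute-force nested-RSS F to 1e-10", {
  res <- ancova(toy_anc$y, toy_anc$g, list(cv = toy_anc$cv))
  X_full <- cbind(model.matrix(~ g + cv, toy_anc)[, -1])
  X_red <- matrix(toy_anc$cv, ncol = 1)
  rss_full <- ols_rss(toy_anc$y, X_full)
  rss_red <- ols_rss(toy_anc$y, X_red)
  df1 <- 2; df2 <- nrow(toy_anc) - 4
  f_oracle <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  expect_equal(res$factor$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$factor$df1, df1)
  expect_equal(res$factor$df2, df2)
})

test_that("ANCOVA without covariates degenerates to one-way ANOVA", {
  res <- ancova(toy_anc$y, toy_anc$g)
  oracle <- anova(aov(y ~ g, data = toy_anc))
  expect_equal(res$factor$F, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(res$factor$p, oracle$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("ANCOVA under the null has F near 1 on average", {
  set.seed(9)
  fs <- replicate(60, {
    g <- factor(sample(letters[1:4], 400, TRUE))
    y <- rnorm(400)
    ancova(y, g, list(cv = rnorm(400)))$factor$F
  })
  expect_lt(abs(mean(fs) - 1), 0.25)
})

test_that("ANCOVA reports empty groups and adjusted means coherently", {
  expect_error(ancova(rnorm(5), factor(rep("a", 5))), "grouping error")
  res <- ancova(toy_anc$y, toy_anc$g, list(cv = toy_anc$cv))
  expect_named(res$adjusted_means, c("a", "b", "c"))
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw - 1e-12))
  expect_true(all(res$posthoc$p_adj <= 1))
})

test_that("interaction model recovers a built-in interaction within 3 SE", {
  set.seed(10)
  n <- 1e5
  x <- rexp(n); sex <- rbinom(n, 1, 0.5)
  b_int <- -0.25
  y <- 1 + 0.5 * x + 0.3 * sex + b_int * (x - mean(x)) * (sex - mean(sex)) + rnorm(n)
  fit <- interaction_model(y, x, sex)
  row <- fit$coefficients[fit$coefficients$term == "exposure_x_sex", ]
  se <- (row$ci_upper - row$ci_lower) / (2 * qt(0.975, fit$df))
  expect_lt(abs(row$B - b_int), 3 * se)
})

test_that("diagnostics match a standard-normal reference at large n", {
  set.seed(11)
  r <- rnorm(1e5)
  g <- factor(sample(c("a", "b", "c"), 1e5, TRUE))
  d <- model_diagnostics(r, g)
  expect_lt(abs(d$skewness), 0.03)
  expect_lt(abs(d$excess_kurtosis), 0.06)
  expect_true(all(diff(d$qq$theoretical) >= 0))
  expect_true(all(diff(d$qq$empirical) >= 0))
})

test_that("Levene p-values are null-uniform and detect a 4:1 variance ratio", {
  set.seed(12)
  p_null <- replicate(200, {
    r <- rnorm(600)
    g <- factor(rep(c("a", "b", "c"), each = 200))
    model_diagnostics(r, g)$levene$p
  })
  ks <- suppressWarnings(ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)

  p_alt <- replicate(100, {
    r <- c(rnorm(500, sd = 2), rnorm(500, sd = 1))
    g <- factor(rep(c("a", "b"), each = 500))
    model_diagnostics(r, g)$levene$p
  })
  expect_gte(mean(p_alt < 0.01), 0.99)
})
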