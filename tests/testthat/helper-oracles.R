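# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Closed-form moments of a normal(mu, sigma) truncated to [a, b].
trunc_normal_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  mean <- mu + sigma * (dnorm(al) - dnorm(be)) / Z
  var <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                      ((dnorm(al) - dnorm(be)) / Z)^2)
  list(mean = mean, var = var, sd = sqrt(var))
}

# Cronbach alpha via the mean inter-item covariance form (k^2 * cbar / varT),
# algebraically identical to the variance form.
alpha_covariance_form <- function(items) {
  k <- ncol(items)
  C <- cov(items)
  cbar <- mean(C[upper.tri(C)])
  k^2 * cbar / sum(C)
}

# ICC(2,1) from the mean squares of a fixed-effects two-way ANOVA fit by aov.
icc21_aov_oracle <- function(s0, s24) {
  n <- length(s0)
  d <- data.frame(y = c(s0, s24),
                  subject = factor(rep(seq_len(n), 2)),
                  occasion = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subject + occasion, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# OLS coefficients by explicit normal equations.
ols_normal_equations <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  solve(t(Xm) %*% Xm, t(Xm) %*% y)[, 1]
}

# Residual sum of squares of an OLS fit by normal equations.
ols_rss <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  sum((y - Xm %*% beta)^2)
}

# Exhaustive permutation p-value for a Pearson correlation on a tiny sample:
# proportion of the n! permutations of y with |r| >= |r_obs|.
permutation_p_exhaustive <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  r_obs <- abs(cor(x, y))
  rs <- vapply(perms(y), function(p) abs(cor(x, p)), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Small deterministic toy datasets -------------------------------------------

# 4-subject, 2-item matrix whose alpha was computed by hand from the k = 2
# formula 2 * (1 - (v1 + v2) / (v1 + v2 + 2c)):
# v1 = 5/3, v2 = 10/3, c = 2 -> alpha = 8/9.
toy_items_2 <- matrix(c(1, 2, 4, 3,
                        2, 1, 5, 4), ncol = 2)
toy_alpha_2 <- 8 / 9

# 6-point toy set for the permutation oracle.
toy_x6 <- c(0.1, 0.9, 1.7, 2.1, 3.0, 4.2)
toy_y6 <- c(5.2, 4.9, 6.3, 5.8, 7.4, 6.9)

# 10-row toy regression dataset (fixed numbers, no RNG).
toy_reg <- data.frame(
  y  = c(3.1, 4.0, 5.2, 4.8, 6.1, 7.0, 6.6, 8.2, 7.9, 9.3),
  x1 = c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0),
  x2 = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
  x3 = c(2.2, 1.9, 3.1, 2.5, 3.8, 4.1, 3.3, 4.9, 4.4, 5.2)
)

# 12-row toy ANCOVA dataset: 3 groups x 4, one covariate.
toy_anc <- data.frame(
  y = c(10.2, 11.1, 9.8, 10.7, 12.3, 13.0, 12.1, 12.9, 14.2, 15.1, 14.0, 14.8),
  g = factor(rep(c("a", "b", "c"), each = 4)),
  cv = c(1.1, 2.0, 0.9, 1.7, 1.4, 2.2, 1.0, 1.9, 1.2, 2.1, 0.8, 1.6)
)

# Shared default config for tests (the shipped calibrated preset).
default_config <- function(...) sim_config(...)
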