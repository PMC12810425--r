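#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] (t transform with n - 2 degrees of
#' freedom), returning a plain list so the value serializes cleanly.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("state error: vectors differ in length")
  if (length(x) < 3L) stop("pearson_r needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined statistic: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Multivariable OLS with standardized coefficients
#'
#' Ordinary least squares via [stats::lm()]. For each predictor the table
#' reports the unstandardized coefficient B, the standardized coefficient
#' `beta = B * SD(predictor) / SD(outcome)`, the 95% t-based confidence
#' interval on B, and the two-sided p-value; model-level fields are R^2,
#' adjusted R^2, n and residual df.
#'
#' @param outcome Numeric response vector.
#' @param predictors Named list or data.frame of numeric predictors.
#' @return An object of class `regression_table`: list with `coefficients`
#'   (data.frame, one row per predictor incl. intercept), `r_squared`,
#'   `adj_r_squared`, `n`, `df`, and the fitted `model`.
#' @export
fit_linear_model <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  n <- length(outcome)
  if (nrow(predictors) != n) stop("state error: predictor length mismatch")
  if (n <= ncol(predictors) + 1L) stop("too few observations for the design")
  dat <- cbind(.outcome = outcome, predictors)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (fit$rank < ncol(predictors) + 1L) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("collinearity error: rank-deficient design (", paste(bad, collapse = ", "), ")")
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- sm$coefficients
  sd_out <- stats::sd(outcome)
  std_beta <- vapply(rownames(co), function(nm) {
    if (nm == "(Intercept)") return(NA_real_)
    co[nm, 1] * stats::sd(predictors[[nm]]) / sd_out
  }, numeric(1))
  tab <- data.frame(
    term = rownames(co),
    B = unname(co[, 1]),
    std_beta = unname(std_beta),
    ci_lower = unname(ci[, 1]),
    ci_upper = unname(ci[, 2]),
    p = unname(co[, 4]),
    row.names = NULL
  )
  structure(list(coefficients = tab,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = n, df = fit$df.residual, model = fit),
            class = "regression_table")
}

#' @export
print.regression_table <- function(x, ...) {
  cat(sprintf("OLS regression (n = %d, R2 = %.3f, adj R2 = %.3f)\n",
              x$n, x$r_squared, x$adj_r_squared))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' ANCOVA with Type-II factor test, adjusted means and Bonferroni post-hocs
#'
#' Fits `outcome ~ factor + covariates` by OLS and tests the factor by the
#' Type-II nested-model comparison (full model vs the model with the factor
#' dropped): `F = ((RSS_reduced - RSS_full)/df1) / (RSS_full/df2)`. Covariate
#' rows carry the analogous drop-one Type-II tests. Adjusted group means are
#' model predictions at the covariate means; post-hoc pairwise group
#' contrasts use the full model's coefficient covariance with Bonferroni
#' adjustment.
#'
#' @param outcome Numeric response.
#' @param groups Factor (or coercible) with >= 2 non-empty levels.
#' @param covariates Named list/data.frame of numeric covariates (may be
#'   empty, in which case the test degenerates to one-way ANOVA).
#' @return An object of class `ancova_table`.
#' @export
ancova <- function(outcome, groups, covariates = NULL) {
  groups <- droplevels(as.factor(groups))
  counts <- table(groups)
  if (length(counts) < 2L) {
    stop("grouping error: need >= 2 non-empty groups; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  covariates <- if (is.null(covariates) || length(covariates) == 0) {
    data.frame(row.names = seq_along(outcome))
  } else as.data.frame(covariates)
  dat <- cbind(.outcome = outcome, .group = groups, covariates)
  full <- stats::lm(.outcome ~ ., data = dat)
  reduced <- if (ncol(covariates)) {
    stats::lm(.outcome ~ . - .group, data = dat)
  } else {
    stats::lm(.outcome ~ 1, data = dat)
  }
  cmp <- stats::anova(reduced, full)
  df1 <- cmp$Df[2]
  df2 <- full$df.residual
  f_factor <- cmp$F[2]
  p_factor <- cmp$`Pr(>F)`[2]

  cov_rows <- NULL
  if (ncol(covariates)) {
    cov_rows <- do.call(rbind, lapply(names(covariates), function(v) {
      red_v <- stats::update(full, stats::as.formula(paste(". ~ . -", v)))
      cc <- stats::anova(red_v, full)
      data.frame(term = v, F = cc$F[2], df1 = cc$Df[2], df2 = df2,
                 p = cc$`Pr(>F)`[2])
    }))
  }

  # adjusted means: predictions at covariate means for each group
  newdat <- data.frame(.group = factor(levels(groups), levels = levels(groups)))
  for (v in names(covariates)) newdat[[v]] <- mean(covariates[[v]])
  adj_means <- stats::setNames(as.numeric(stats::predict(full, newdat)),
                               levels(groups))

  # Bonferroni-adjusted pairwise contrasts on the group dummies
  lev <- levels(groups)
  cf <- stats::coef(full)
  V <- stats::vcov(full)
  dummy <- function(l) if (l == lev[1]) NULL else paste0(".group", l)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- length(pairs)
  post <- do.call(rbind, lapply(pairs, function(pr) {
    contrast <- stats::setNames(numeric(length(cf)), names(cf))
    d1 <- dummy(pr[1]); d2 <- dummy(pr[2])
    if (!is.null(d1)) contrast[d1] <- 1
    if (!is.null(d2)) contrast[d2] <- contrast[d2] - 1
    est <- sum(contrast * cf)
    se <- sqrt(drop(t(contrast) %*% V %*% contrast))
    tval <- est / se
    praw <- 2 * stats::pt(-abs(tval), df2)
    data.frame(group1 = pr[1], group2 = pr[2], diff = est, se = se,
               t = tval, p_raw = praw, p_adj = min(1, praw * m))
  }))

  structure(list(
    factor = list(F = f_factor, df1 = df1, df2 = df2, p = p_factor),
    covariates = cov_rows,
    adjusted_means = adj_means,
    group_counts = as.list(counts),
    posthoc = post,
    model = full
  ), class = "ancova_table")
}

#' @export
print.ancova_table <- function(x, ...) {
  cat(sprintf("ANCOVA factor test: F(%d, %d) = %.3f, p = %.4g\n",
              x$factor$df1, x$factor$df2, x$factor$F, x$factor$p))
  cat("adjusted means:\n")
  print(round(x$adjusted_means, 3))
  invisible(x)
}

#' Exposure-by-sex interaction model
#'
#' Appends the product of mean-centered exposure and sex to the covariate
#' model and refits by the same OLS machinery; the `exposure_x_sex` row of
#' the returned table is the interaction term.
#'
#' @param outcome Numeric response.
#' @param exposure Numeric primary predictor.
#' @param sex 0/1 sex indicator.
#' @param covariates Named list/data.frame of additional numeric covariates.
#' @return A `regression_table` including the `exposure_x_sex` term.
#' @export
interaction_model <- function(outcome, exposure, sex, covariates = NULL) {
  preds <- data.frame(exposure = exposure, sex = sex)
  if (!is.null(covariates) && length(covariates)) {
    preds <- cbind(preds, as.data.frame(covariates))
  }
  preds$exposure_x_sex <- (exposure - mean(exposure)) * (sex - mean(sex))
  fit_linear_model(outcome, preds)
}

#' Model diagnostics: residual shape, homogeneity, Q-Q pairs
#'
#' Sample skewness and excess kurtosis of the residuals; the Brown-Forsythe
#' variance-homogeneity test (Levene with median centering) across exposure
#' strata via a one-way ANOVA on `|residual - group median|`; and sorted
#' theoretical-vs-empirical normal quantile pairs for Q-Q plotting.
#'
#' @param residuals Numeric residual vector (length >= 3).
#' @param groups Factor of exposure strata for the homogeneity test.
#' @param n_qq Number of Q-Q quantile pairs to return.
#' @return List with `skewness`, `excess_kurtosis`, `levene` (`F`, `df1`,
#'   `df2`, `p`), and `qq` (data.frame `theoretical`, `empirical`).
#' @export
model_diagnostics <- function(residuals, groups, n_qq = 100) {
  n <- length(residuals)
  if (n < 3L) stop("state error: need at least 3 residuals")
  z <- residuals - mean(residuals)
  m2 <- mean(z^2); m3 <- mean(z^3); m4 <- mean(z^4)
  skew <- m3 / m2^1.5
  exkurt <- m4 / m2^2 - 3

  groups <- droplevels(as.factor(groups))
  med <- tapply(residuals, groups, stats::median)
  absdev <- abs(residuals - med[as.character(groups)])
  lev_fit <- stats::lm(absdev ~ groups)
  lev <- stats::anova(lev_fit)
  levene <- list(F = lev$`F value`[1], df1 = lev$Df[1], df2 = lev$Df[2],
                 p = lev$`Pr(>F)`[1])

  probs <- (seq_len(n_qq) - 0.5) / n_qq
  qq <- data.frame(
    theoretical = stats::qnorm(probs, mean = mean(residuals), sd = stats::sd(residuals)),
    empirical = unname(stats::quantile(residuals, probs, type = 7))
  )
  list(skewness = skew, excess_kurtosis = exkurt, levene = levene, qq = qq)
}
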