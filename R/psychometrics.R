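#' Cronbach's alpha
#'
#' Internal-consistency reliability from the item-variance decomposition:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row totals))`, with
#' sample (n-1) variances. Algebraically identical to the mean inter-item
#' covariance form `k^2 * cbar / var(total)`; the test suite checks the
#' identity on every matrix it touches.
#'
#' @param items Numeric matrix, subjects x items (k >= 2 columns, >= 2 rows).
#' @return Alpha (a real number <= 1; can be negative for inconsistent items).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L) stop("cronbach_alpha needs at least 2 items")
  if (nrow(items) < 2L) stop("cronbach_alpha needs at least 2 subjects")
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0) stop("undefined statistic: zero total-score variance")
  item_vars <- apply(items, 2, stats::var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}

#' Test-retest intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, computed
#' from the mean squares of the subjects x occasions table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 occasions.
#' Alternative forms: `type = "consistency"` drops the occasion-variance term
#' (ICC(3,1)).
#'
#' @param s0 Scores at the first occasion (baseline).
#' @param s24 Scores at the second occasion (Week 24).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"` (ICC(3,1)).
#' @return The intraclass correlation.
#' @export
icc_test_retest <- function(s0, s24, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(s0) != length(s24)) stop("state error: score vectors differ in length")
  n <- length(s0)
  if (n < 3L) stop("icc_test_retest needs at least 3 subjects")
  y <- cbind(s0, s24)
  k <- 2L
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Convergent validity of severity against density
#'
#' Pearson correlation between Week-24 SAHL totals and Week-24 follicular
#' density, reported signed as computed. Under the generating model the sign
#' is negative (higher severity goes with lower density); comparisons against
#' magnitude-style reported values should use `abs()`.
#'
#' @param s24 Week-24 SAHL totals.
#' @param d24 Week-24 densities.
#' @return The signed Pearson correlation.
#' @export
convergent_validity <- function(s24, d24) {
  if (length(s24) != length(d24)) stop("state error: vectors differ in length")
  if (length(s24) < 3L) stop("convergent_validity needs at least 3 subjects")
  if (stats::sd(s24) == 0 || stats::sd(d24) == 0) {
    stop("undefined statistic: zero variance input")
  }
  stats::cor(s24, d24)
}

#' Reliability and validity report for a completed cohort
#'
#' @param cohort A completed cohort with baseline and Week-24 SAHL items.
#' @return List with `alpha_baseline`, `alpha_week24`, `icc_test_retest`
#'   and `convergent_r` (signed).
#' @export
reliability_report <- function(cohort) {
  b_items <- as.matrix(cohort[, grep("^sahl_b\\d+$", names(cohort)), drop = FALSE])
  w_items <- as.matrix(cohort[, grep("^sahl_w\\d+$", names(cohort)), drop = FALSE])
  if (ncol(b_items) < 2L || ncol(w_items) < 2L) {
    stop("state error: item-level SAHL columns missing")
  }
  list(
    alpha_baseline = cronbach_alpha(b_items),
    alpha_week24 = cronbach_alpha(w_items),
    icc_test_retest = icc_test_retest(cohort$sahl_total_baseline,
                                      cohort$sahl_total_week24),
    convergent_r = convergent_validity(cohort$sahl_total_week24,
                                       cohort$density_week24)
  )
}
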