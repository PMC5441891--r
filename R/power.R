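#' Power of the t test for a single coefficient in multiple regression
#'
#' Power to detect a non-zero coefficient explaining a given partial R^2 in
#' a linear regression with `n_predictors` predictors, at sample size `n`.
#' The effect size is f^2 = pr^2 / (1 - pr^2); the test statistic follows a
#' noncentral t distribution with noncentrality sqrt(f^2 * n) and
#' n - n_predictors - 1 degrees of freedom, compared against the two-tailed
#' (or one-tailed) alpha critical value.
#'
#' @param n Sample size (must leave at least 1 residual df).
#' @param partial_r2 Partial R^2 of the tested predictor, in (0, 1).
#' @param n_predictors Number of predictors in the model.
#' @param alpha Type-I error rate.
#' @param two_tailed Two-tailed test (default) or one-tailed.
#' @return Power in [0, 1].
#' @export
#' @examples
#' regression_coef_power(50, partial_r2 = 0.15, n_predictors = 9)
regression_coef_power <- function(n, partial_r2 = 0.15, n_predictors = 9L,
                                  alpha = 0.05, two_tailed = TRUE) {
  assert_scalar_number(partial_r2, "partial_r2", 1e-12, 1 - 1e-12)
  assert_scalar_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  df <- n - n_predictors - 1
  if (df < 1) stop_cocktailr("Sample size leaves no residual degrees of freedom.")
  f2 <- partial_r2 / (1 - partial_r2)
  ncp <- sqrt(f2 * n)
  if (two_tailed) {
    crit <- qt(1 - alpha / 2, df)
    1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  } else {
    crit <- qt(1 - alpha, df)
    1 - pt(crit, df, ncp)
  }
}

#' Minimum sample size for a target power
#'
#' Smallest N for which [regression_coef_power()] reaches the target power.
#' With the defaults (partial R^2 = 0.15, alpha = 0.05 two-tailed, power
#' 0.80, nine predictors) the answer is N = 47.
#'
#' @inheritParams regression_coef_power
#' @param power Target power in (0, 1).
#' @param n_max Upper search bound; exceeding it raises an error
#'   (unattainable power).
#' @return The minimum sample size (integer).
#' @export
#' @examples
#' min_sample_size()  # 47
min_sample_size <- function(partial_r2 = 0.15, alpha = 0.05, power = 0.80,
                            n_predictors = 9L, two_tailed = TRUE,
                            n_max = 1e6) {
  assert_scalar_number(power, "power", 1e-12, 1 - 1e-12)
  n <- n_predictors + 2
  while (n <= n_max) {
    if (regression_coef_power(n, partial_r2, n_predictors, alpha,
                              two_tailed) >= power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop_cocktailr(sprintf("Target power %.2f not attainable below n = %g.",
                         power, n_max),
                 class = "cocktailr_domain_error")
}
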