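#' Pearson partial correlation controlling for a covariate
#'
#' Correlates the residuals of `x` and `y` after regressing each on the
#' control variable (with intercept). The p value comes from
#' t = rho * sqrt((n - 3) / (1 - rho^2)) on n - 3 degrees of freedom,
#' two-tailed.
#'
#' @param data A data frame.
#' @param x,y Names of the two columns to correlate.
#' @param control Name of the covariate column to partial out.
#' @return A one-row tibble: `x`, `y`, `control`, `estimate`,
#'   `statistic`, `p.value`, `n`.
#' @export
#' @examples
#' d <- data.frame(a = rnorm(30), z = rnorm(30))
#' d$b <- d$a + 0.5 * d$z + rnorm(30)
#' partial_correlation(d, "a", "b", "z")
partial_correlation <- function(data, x, y, control) {
  v <- as.data.frame(data)[, c(x, y, control)]
  n <- nrow(v)
  if (n < 4L) stop_cocktailr("Need at least 4 observations.")
  rx <- residuals(lm(v[[1L]] ~ v[[3L]]))
  ry <- residuals(lm(v[[2L]] ~ v[[3L]]))
  if (sd(rx) < 1e-10 * max(sd(v[[1L]]), 1e-300) ||
      sd(ry) < 1e-10 * max(sd(v[[2L]]), 1e-300)) {
    stop_cocktailr("Zero residual variance after partialling out the control.",
                   class = "cocktailr_degenerate_error")
  }
  rho <- cor(rx, ry)
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  tibble::tibble(
    x = x, y = y, control = control,
    estimate = rho, statistic = tstat,
    p.value = 2 * pt(-abs(tstat), df = n - 3),
    n = n
  )
}

#' Pairwise partial correlation matrix controlling for a covariate
#'
#' All pairwise partial correlations among `vars` controlling for
#' `control`, plus (optionally) the plain Pearson correlation of each
#' variable with the control itself.
#'
#' @param data A data frame.
#' @param vars Columns to correlate pairwise.
#' @param control Covariate to partial out.
#' @param with_control Append each variable's zero-order correlation with
#'   the control (its p value from the usual Pearson test).
#' @return A tibble in long form: `x`, `y`, `estimate`, `statistic`,
#'   `p.value`, `n` (one row per unordered pair).
#' @export
partial_correlation_matrix <- function(data, vars, control,
                                       with_control = TRUE) {
  pairs <- utils::combn(vars, 2L, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    partial_correlation(data, pr[1], pr[2], control)
  })
  if (with_control) {
    d <- as.data.frame(data)
    ctl <- purrr::map_dfr(vars, function(v) {
      ct <- stats::cor.test(d[[v]], d[[control]])
      tibble::tibble(x = v, y = control, control = NA_character_,
                     estimate = unname(ct$estimate),
                     statistic = unname(ct$statistic),
                     p.value = ct$p.value, n = nrow(d))
    })
    out <- dplyr::bind_rows(out, ctl)
  }
  out
}
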