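#' Absolute-agreement intraclass correlation, ICC(A,k)
#'
#' Test-retest reliability of the average of k measurements under the
#' two-way mixed model with absolute agreement: from the two-way ANOVA
#' decomposition (rows = subjects, columns = measurements),
#' `ICC(A,k) = (MS_rows - MS_error) / (MS_rows + (MS_cols - MS_error) / n)`.
#' Unlike consistency ICCs, systematic offsets between measurements lower
#' the coefficient. Negative estimates are reported as computed, with a
#' flag, rather than floored at zero.
#'
#' @param data Numeric matrix or data frame, subjects x k measurements
#'   (no missing cells; n >= 3, k >= 2). An optional `subject_id` column is
#'   dropped.
#' @param average_of_k Must be `TRUE`: this function reports the
#'   average-measures form (the single-measure form is out of scope).
#' @return An object of class `icc_result`: `value`, `variant` (e.g.
#'   "A,2"), mean squares, `n`, `k`, `negative` flag.
#' @export
#' @examples
#' m <- cbind(c(1, 2, 3, 4, 5, 6), c(1.1, 2.0, 3.2, 3.9, 5.1, 6.0))
#' icc_absolute_agreement(m)
icc_absolute_agreement <- function(data, average_of_k = TRUE) {
  stopifnot(isTRUE(average_of_k))
  if (is.data.frame(data)) {
    data <- data[, setdiff(names(data), "subject_id"), drop = FALSE]
  }
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stop_cocktailr("Need k >= 2 measurements.")
  if (n < 3L) stop_cocktailr("Need at least 3 subjects.")
  if (anyNA(m)) {
    stop_cocktailr("Missing cells are not allowed (no imputation is performed).",
                   class = "cocktailr_missing_error")
  }
  gm <- mean(m)
  if (sum((m - gm)^2) < 1e-300) {
    stop_cocktailr("Total variance is zero; the ICC is undefined.",
                   class = "cocktailr_degenerate_error")
  }
  ms_rows <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  ms_err <- (sum((m - gm)^2) - k * sum((rowMeans(m) - gm)^2) -
               n * sum((colMeans(m) - gm)^2)) / ((n - 1) * (k - 1))
  value <- (ms_rows - ms_err) / (ms_rows + (ms_cols - ms_err) / n)
  structure(
    list(value = value, variant = sprintf("A,%d", k),
         ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
         n = n, k = k, negative = value < 0),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f  (n = %d, k = %d)%s\n", x$variant, x$value,
              x$n, x$k, if (x$negative) "  [negative estimate]" else ""))
  invisible(x)
}

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(variant = x$variant, estimate = x$value, n = x$n, k = x$k,
                 ms_rows = x$ms_rows, ms_cols = x$ms_cols,
                 ms_error = x$ms_error)
}

#' Reliability report across the repeatable measures
#'
#' Computes ICC(A,k) for every per-block measure table produced by
#' [score_blocks()], using all available blocks of each measure (k = 2 for
#' most measures, k = 3 for the masked DL) and dropping subjects with a
#' missing block value (excluded tracks).
#'
#' @param block_scores Named list from [score_blocks()].
#' @return A tibble: `measure`, `variant`, `estimate`, `n`, `k`.
#' @export
reliability_report <- function(block_scores) {
  purrr::map_dfr(names(block_scores), function(ms) {
    tb <- block_scores[[ms]]
    m <- as.matrix(tb[, setdiff(names(tb), "subject_id"), drop = FALSE])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    res <- icc_absolute_agreement(m)
    tibble::tibble(measure = ms, variant = res$variant,
                   estimate = res$value, n = res$n, k = res$k)
  })
}
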