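#' Arcsine-square-root transform of a proportion
#'
#' Variance-stabilising transform applied to proportion-correct scores
#' before regression/ANOVA: `asin(sqrt(p))`, strictly increasing on [0, 1]
#' with range [0, pi/2].
#'
#' @param p Proportions in [0, 1].
#' @return Transformed values.
#' @export
#' @examples
#' arcsin_sqrt(c(0, 0.25, 1))  # 0, pi/6, pi/2
arcsin_sqrt <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_cocktailr("Proportions must lie in [0, 1].", class = "cocktailr_domain_error")
  }
  asin(sqrt(p))
}

#' Speech recognition score from sentence-task trials
#'
#' Computes, per subject, the word-level proportion correct in each retained
#' block, averages the per-block proportions, and applies the
#' arcsine-square-root transform. Block 1 is excluded by default (practice
#' effect), so the default score averages blocks 2 and 3.
#'
#' @param trials Sentence-task trial tibble (rows with `task == "sentence"`
#'   are selected automatically) carrying `subject_id`, `block` and the five
#'   word-correctness flags `word1` ... `word5`.
#' @param blocks_used Blocks entering the score (default 2:3).
#' @return A tibble: `subject_id`, `srs_prop` (mean proportion correct),
#'   `SRS` (transformed).
#' @export
compute_srs <- function(trials, blocks_used = c(2L, 3L)) {
  st <- dplyr::filter(trials, .data$task == "sentence")
  word_cols <- grep("^word\\d+$", names(st), value = TRUE)
  if (nrow(st) == 0L || length(word_cols) == 0L) {
    stop_cocktailr("No sentence trials with word-correctness flags found.")
  }
  have <- dplyr::distinct(st, .data$subject_id, .data$block)
  need <- tidyr::expand_grid(subject_id = unique(st$subject_id),
                             block = blocks_used)
  missing <- dplyr::anti_join(need, have, by = c("subject_id", "block"))
  if (nrow(missing) > 0L) {
    stop_cocktailr(sprintf(
      "Missing sentence block(s): %s.",
      paste(sprintf("subject %s block %s", missing$subject_id, missing$block),
            collapse = "; ")
    ), class = "cocktailr_scoring_error")
  }
  st |>
    dplyr::filter(.data$block %in% blocks_used) |>
    dplyr::select("subject_id", "block", dplyr::all_of(word_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(word_cols), values_to = "ok") |>
    dplyr::summarise(p = mean(.data$ok),
                     .by = c("subject_id", "block")) |>
    dplyr::summarise(srs_prop = mean(.data$p), .by = "subject_id") |>
    dplyr::mutate(SRS = arcsin_sqrt(.data$srs_prop))
}

#' Flanker-task measures: processing speed and interference
#'
#' Keeps correct trials with RTs between 200 and 3000 ms from the retained
#' blocks (block 1 excluded by default), log-transforms the RTs, and
#' computes per subject the mean log RT on neutral trials (`RT_neutral`, a
#' processing-speed measure) and the flanker interference (`Int_Flanker`):
#' mean log RT (incompatible) minus mean log RT (neutral), computed within
#' each object condition and averaged across the two object conditions with
#' equal weight.
#'
#' @param trials Flanker trial tibble with `subject_id`, `block`,
#'   `distractor`, `object`, `rt_ms`, `correct`.
#' @param blocks_used Blocks entering the scores (default 2:3).
#' @param rt_range Inclusive RT window in ms (default c(200, 3000)).
#' @return A tibble: `subject_id`, `RT_neutral` (log-ms), `Int_Flanker`
#'   (log-RT difference).
#' @export
compute_flanker_measures <- function(trials, blocks_used = c(2L, 3L),
                                     rt_range = c(200, 3000)) {
  ft <- trials |>
    dplyr::filter(.data$task == "flanker",
                  .data$block %in% blocks_used,
                  .data$correct,
                  .data$rt_ms >= rt_range[1], .data$rt_ms <= rt_range[2])
  if (nrow(ft) == 0L) {
    stop_cocktailr("No flanker trials survive the filters.",
                   class = "cocktailr_scoring_error")
  }
  cell <- ft |>
    dplyr::summarise(m = mean(log(.data$rt_ms)), n = dplyr::n(),
                     .by = c("subject_id", "distractor", "object"))
  full <- tidyr::expand_grid(subject_id = unique(trials$subject_id),
                             distractor = c("neutral", "incompatible"),
                             object = c("same", "different"))
  empty <- dplyr::anti_join(full, cell,
                            by = c("subject_id", "distractor", "object"))
  if (nrow(empty) > 0L) {
    stop_cocktailr(sprintf(
      "No surviving flanker trials in cell(s): %s.",
      paste(sprintf("subject %s %s/%s", empty$subject_id, empty$distractor,
                    empty$object), collapse = "; ")
    ), class = "cocktailr_scoring_error")
  }
  interference <- cell |>
    tidyr::pivot_wider(names_from = "distractor", values_from = c("m", "n")) |>
    dplyr::mutate(int = .data$m_incompatible - .data$m_neutral) |>
    dplyr::summarise(Int_Flanker = mean(.data$int), .by = "subject_id")
  neutral <- ft |>
    dplyr::filter(.data$distractor == "neutral") |>
    dplyr::summarise(RT_neutral = mean(log(.data$rt_ms)), .by = "subject_id")
  dplyr::left_join(neutral, interference, by = "subject_id")
}

#' Audiometric summary measures
#'
#' Per-ear mean threshold over the six octave frequencies 125 Hz-4 kHz;
#' `PTA_BE` is the better (lower) of the two ear means and `HL_diff` the
#' mean absolute left-right threshold difference across frequencies.
#' Absolute differences are used because signed asymmetries would cancel
#' across frequencies; set `signed = TRUE` for the signed mean instead.
#'
#' @param audiograms Long tibble from [simulate_audiograms()] (or same
#'   shape): `subject_id`, `ear`, `freq_hz`, `threshold_db`, with all six
#'   frequencies per ear.
#' @param signed Use the signed mean difference instead of mean |L - R|.
#' @return A tibble: `subject_id`, `PTA_BE`, `HL_diff` (both dB).
#' @export
compute_audiogram_measures <- function(audiograms, signed = FALSE) {
  counts <- audiograms |>
    dplyr::summarise(n = dplyr::n_distinct(.data$freq_hz),
                     .by = c("subject_id", "ear"))
  if (any(counts$n != 6L) || !all(c("left", "right") %in% audiograms$ear)) {
    stop_cocktailr("Each subject needs thresholds at all 6 octave frequencies for both ears.",
                   class = "cocktailr_scoring_error")
  }
  wide <- audiograms |>
    tidyr::pivot_wider(names_from = "ear", values_from = "threshold_db")
  wide |>
    dplyr::summarise(
      PTA_BE = min(mean(.data$left), mean(.data$right)),
      HL_diff = if (signed) mean(.data$left - .data$right)
                else mean(abs(.data$left - .data$right)),
      .by = "subject_id"
    )
}

#' Sentence-span score (partial-credit scoring)
#'
#' A consonant is credited only when reproduced in its correct serial
#' position. Per-list proportions correct are averaged over the 10 lists
#' with equal weight (partial credit), then arcsine-square-root transformed.
#'
#' @param trials Span trial tibble: `subject_id`, `block` (list), `trial`
#'   (serial position), `presented`, `recalled`.
#' @return A tibble: `subject_id`, `span_prop`, `SS_Pcorr` (transformed).
#' @export
compute_span_score <- function(trials) {
  sp <- dplyr::filter(trials, .data$task == "span")
  if (nrow(sp) == 0L) {
    stop_cocktailr("No span trials found.", class = "cocktailr_scoring_error")
  }
  if (anyNA(sp$recalled) || anyNA(sp$presented)) {
    stop_cocktailr("Span responses must have the presented length (no skipped positions).",
                   class = "cocktailr_scoring_error")
  }
  sp |>
    dplyr::summarise(p = mean(.data$recalled == .data$presented),
                     .by = c("subject_id", "block")) |>
    dplyr::summarise(span_prop = mean(.data$p), .by = "subject_id") |>
    dplyr::mutate(SS_Pcorr = arcsin_sqrt(.data$span_prop))
}

#' Repeated-measures ANOVA on blocks (multivariate approach)
#'
#' Exact Hotelling T-squared test of the within-subject block effect on
#' difference contrasts (each block minus block 1), the multivariate
#' approach to the one-way repeated-measures ANOVA. For two blocks the F
#' statistic equals the squared paired t with df (1, n - 1). Cohen's d_z
#' (mean difference / SD of differences) is reported for the two-block
#' case.
#'
#' @param block_matrix Numeric matrix or data frame, subjects x blocks.
#' @return A tibble: `statistic` (F), `df1`, `df2`, `p.value`, `d_z` (NA
#'   unless exactly 2 blocks).
#' @export
#' @examples
#' m <- cbind(b1 = c(1, 2, 3, 4), b2 = c(2, 2, 4, 5))
#' rm_anova_block_test(m)
rm_anova_block_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stop_cocktailr("Need at least 2 blocks.")
  if (n < k + 1L) stop_cocktailr("Need at least blocks + 1 subjects.")
  D <- m[, -1L, drop = FALSE] - m[, 1L]
  S <- stats::cov(D)
  if (max(abs(S)) < 1e-300 || abs(det(S)) < 1e-300) {
    stop_cocktailr("Within-subject contrasts have (numerically) zero variance.",
                   class = "cocktailr_degenerate_error")
  }
  dbar <- colMeans(D)
  T2 <- n * drop(t(dbar) %*% solve(S, dbar))
  df1 <- k - 1L
  df2 <- n - k + 1L
  Fstat <- T2 * df2 / ((n - 1) * df1)
  tibble::tibble(
    statistic = Fstat, df1 = df1, df2 = df2,
    p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
    d_z = if (k == 2L) mean(D[, 1L]) / sd(D[, 1L]) else NA_real_
  )
}
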