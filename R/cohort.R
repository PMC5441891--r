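#' Generate a cohort of virtual listeners with correlated latent abilities
#'
#' Draws one multivariate Gaussian latent vector per subject under the
#' configured trait correlation matrix, then maps each trait to its native
#' units through its link function (a Gaussian copula): probabilities through
#' the logistic, strictly positive quantities through `exp`, the
#' interaural-phase threshold through `10^` with a 180-degree ceiling, and
#' age through the uniform quantile over `age_range`. The masked intensity DL
#' is constructed as quiet DL plus the (positive) masker-induced elevation,
#' so `dl_masked_true >= dl_quiet_true` always holds.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same
#'   (config, seed) always yields the identical cohort.
#'
#' @return A tibble with one row per subject: `subject_id`, `age`, the
#'   latent truths (`word_intelligibility`, `dl_quiet_true`, `dl_elev_true`,
#'   `dl_masked_true`, `ipd_threshold_true`, `flanker_effect_true`,
#'   `base_log_rt`, `span_recall_prob`, `pta_be_true`, `hl_diff_true`) and
#'   the three latent SSQ subscale means.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 4), seed = 1)
#' coh$word_intelligibility
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) {
    stop_cocktailr("Supply a `seed` (or set it in the config) so cohorts are reproducible.",
                   class = "cocktailr_config_error")
  }
  n <- config$n_subjects
  # one substream per subject, so growing the cohort never perturbs the
  # latents of existing subjects
  L <- chol(config$trait_correlations)
  z <- matrix(NA_real_, nrow = n, ncol = 13L)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i, 1L))
    z[i, ] <- rnorm(13L) %*% L
  }
  colnames(z) <- trait_names()
  sc <- config$trait_scales

  native <- lapply(trait_names(), function(tr) {
    row <- sc[sc$trait == tr, ]
    l <- unname(z[, tr])
    switch(row$link,
      identity = row$mean + row$sd * l,
      log      = exp(row$mean + row$sd * l),
      log10    = 10^(row$mean + row$sd * l),
      logit    = plogis(row$mean + row$sd * l),
      logit01  = 0.1 + 0.9 * plogis(row$mean + row$sd * l),
      uniform  = qunif(pnorm(l), config$age_range[1], config$age_range[2]),
      stop_cocktailr(sprintf("Unknown link '%s' for trait '%s'.", row$link, tr))
    )
  })
  names(native) <- trait_names()

  # Keep the normal-hearing invariants of the default cohort: audiometric
  # thresholds below 20 dB HL and bounded interaural asymmetry. Truncation
  # bounds are documented in the methods vignette.
  pta <- pmin(pmax(native$pta_be, -10), 10)
  hld <- pmin(pmax(native$hl_diff, 0.2), 7)
  ipd <- pmin(native$tfs, 180)

  tibble::tibble(
    subject_id = seq_len(n),
    age = native$age,
    word_intelligibility = native$speech,
    dl_quiet_true = native$dl_quiet,
    dl_elev_true = native$dl_elev,
    dl_masked_true = native$dl_quiet + native$dl_elev,
    ipd_threshold_true = ipd,
    flanker_effect_true = native$int_flanker,
    base_log_rt = native$rt_neutral,
    span_recall_prob = native$span,
    pta_be_true = pta,
    hl_diff_true = hld,
    ssq_speech_true = pmin(pmax(native$ssq_speech, 0), 10),
    ssq_spatial_true = pmin(pmax(native$ssq_spatial, 0), 10),
    ssq_qualities_true = pmin(pmax(native$ssq_qualities, 0), 10)
  )
}

#' Simulate audiograms at octave frequencies 125 Hz to 4 kHz
#'
#' Builds per-ear thresholds from each subject's latent pure-tone average and
#' interaural asymmetry: both ears share the subject's mean level plus a
#' fixed zero-sum frequency contour, and the two ears differ by exactly the
#' latent asymmetry at each frequency with alternating sign, so that the
#' better-ear average equals `pta_be_true` and the mean absolute interaural
#' difference equals `hl_diff_true` by construction.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A long tibble: `subject_id`, `ear` ("left"/"right"), `freq_hz`,
#'   `threshold_db` (dB HL).
#' @export
simulate_audiograms <- function(cohort) {
  freqs <- c(125, 250, 500, 1000, 2000, 4000)
  contour <- c(-2, -1, 0, 0, 1, 2)     # zero-sum shape across frequency
  signs <- c(1, -1, 1, -1, 1, -1)      # balanced interaural asymmetry
  ns <- nrow(cohort)
  base <- rep(cohort$pta_be_true, each = 6L) + rep(contour, ns)
  half <- rep(signs, ns) * rep(cohort$hl_diff_true, each = 6L) / 2
  tibble::new_tibble(list(
    subject_id = rep(cohort$subject_id, each = 12L),
    ear = rep(rep(c("left", "right"), each = 6L), ns),
    freq_hz = rep(freqs, 2L * ns),
    threshold_db = as.numeric(rbind(matrix(base + half, nrow = 6L),
                                    matrix(base - half, nrow = 6L)))
  ), nrow = 12L * ns)
}
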