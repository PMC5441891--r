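#' Latent trait names used by the cohort generator
#'
#' The thirteen latent traits of a simulated listener, in the fixed order used
#' by the trait correlation matrix: word intelligibility in the multi-talker
#' sentence task (`speech`), masker-induced intensity-DL elevation
#' (`dl_elev`), flanker interference (`int_flanker`), interaural-phase
#' threshold (`tfs`), better-ear pure-tone average (`pta_be`), interaural
#' threshold asymmetry (`hl_diff`), intensity DL in quiet (`dl_quiet`),
#' neutral-condition log response time (`rt_neutral`), sentence-span recall
#' probability (`span`), the three SSQ subscales, and `age`.
#'
#' @return Character vector of length 13.
#' @export
trait_names <- function() {
  c("speech", "dl_elev", "int_flanker", "tfs", "pta_be", "hl_diff",
    "dl_quiet", "rt_neutral", "span", "ssq_speech", "ssq_spatial",
    "ssq_qualities", "age")
}

#' Default latent trait correlation matrix
#'
#' An approximate empirical correlation structure for the test battery,
#' treating published age-partialled pairwise associations between the
#' measures as plain latent correlations (see the methods vignette for why
#' this is an approximation and how to supply your own matrix). The matrix is
#' symmetric with unit diagonal and is positive definite (smallest eigenvalue
#' about 0.16), so no repair is ever applied.
#'
#' @return A 13 x 13 correlation matrix over [trait_names()].
#' @export
default_trait_correlations <- function() {
  tn <- trait_names()
  R <- diag(13)
  dimnames(R) <- list(tn, tn)
  fill <- function(R, row, vals) {
    i <- match(row, tn)
    idx <- seq(i + 1L, 13L)
    R[i, idx] <- vals
    R[idx, i] <- vals
    R
  }
  R <- fill(R, "speech",
            c(-0.374, -0.149, -0.353, 0.060, -0.163, -0.244, -0.232, 0.338,
              0.121, 0.083, 0.230, 0.033))
  R <- fill(R, "dl_elev",
            c(-0.047, 0.038, 0.030, -0.083, -0.045, 0.092, -0.255, -0.302,
              -0.049, -0.178, -0.045))
  R <- fill(R, "int_flanker",
            c(-0.081, -0.018, -0.234, -0.032, -0.094, -0.112, -0.141, -0.098,
              -0.112, 0.045))
  R <- fill(R, "tfs",
            c(0.034, -0.023, 0.399, 0.312, -0.177, -0.149, -0.314, -0.352,
              0.027))
  R <- fill(R, "pta_be",
            c(-0.292, -0.083, -0.010, -0.092, 0.136, 0.082, 0.097, -0.248))
  R <- fill(R, "hl_diff", c(0.195, 0.038, 0.087, 0.274, 0.198, 0.119, 0.227))
  R <- fill(R, "dl_quiet", c(0.383, -0.115, -0.008, -0.118, -0.130, 0.082))
  R <- fill(R, "rt_neutral", c(-0.198, -0.087, -0.135, -0.011, 0.217))
  R <- fill(R, "span", c(-0.011, 0.081, 0.053, -0.380))
  R <- fill(R, "ssq_speech", c(0.707, 0.728, 0.040))
  R <- fill(R, "ssq_spatial", c(0.701, 0.123))
  R <- fill(R, "ssq_qualities", c(0.058))
  R
}

#' Default per-trait locations and scales on their link scales
#'
#' One row per latent trait: the link used by the Gaussian copula
#' (`identity`, `log`, `log10`, `logit`, `logit01` for the word
#' probability bounded to [0.1, 1], or `uniform` for age) and the
#' location/scale on that link scale. See the methods vignette for how the
#' defaults were chosen.
#'
#' @return A tibble with columns `trait`, `link`, `mean`, `sd`.
#' @export
default_trait_scales <- function() {
  # Location/scale of each latent trait on its link scale. Traits with
  # bounded native support are parametrised on a link scale (logit for
  # probabilities, log for strictly positive quantities, log10 for the IPD
  # threshold in degrees) so that the Gaussian copula maps into the support
  # exactly. `age` is mapped to a uniform over `age_range` and ignores
  # mean/sd. Values are the package's documented defaults for a young
  # normal-hearing cohort (see the methods vignette).
  tibble::tribble(
    ~trait,          ~link,       ~mean,          ~sd,
    "speech",        "logit01",   0.0,            0.55,   # word p in [0.1, 1]
    "dl_elev",       "log",       log(6),         0.55,   # dB, > 0
    "int_flanker",   "log",       log(0.09),      0.70,   # log-RT units, > 0
    "tfs",           "log10",     log10(20),      0.35,   # degrees, (0, 180]
    "pta_be",        "identity",  5.0,            4.0,    # dB HL
    "hl_diff",       "log",       log(3),         0.50,   # dB, > 0
    "dl_quiet",      "identity",  2.0,            2.5,    # dB (10log10 dI/I)
    "rt_neutral",    "identity",  log(550),       0.12,   # log-ms
    "span",          "logit",     qlogis(0.7),    0.80,   # recall probability
    "ssq_speech",    "identity",  7.16,           1.43,   # 0-10 rating
    "ssq_spatial",   "identity",  6.95,           1.39,
    "ssq_qualities", "identity",  7.82,           1.18,
    "age",           "uniform",   NA_real_,       NA_real_
  )
}

#' Default per-task block and trial counts
#'
#' Three sentence blocks of 50 five-word trials; two quiet and three
#' masked intensity tracks; two interaural-phase tracks; three flanker
#' blocks of 16 conditions x 4 repetitions; two span lists at each length
#' 3-7.
#'
#' @return A named list of design counts.
#' @export
default_task_design <- function() {
  list(
    sentence_blocks = 3L, sentence_trials = 50L, sentence_words = 5L,
    dl_quiet_blocks = 2L, dl_masked_blocks = 3L,
    tfs_blocks = 2L,
    flanker_blocks = 3L, flanker_reps = 4L,
    span_lengths = 3:7, span_reps = 2L
  )
}

#' Configuration for a simulated listener cohort
#'
#' Bundles everything the synthetic-data generator needs: the cohort size,
#' the latent trait correlation matrix, per-trait locations/scales on their
#' link scales, the age range, per-task block/trial counts, practice
#' penalties, and the simulated observers' psychometric slopes.
#'
#' @param n_subjects Number of simulated listeners (>= 1).
#' @param trait_correlations Symmetric positive semi-definite correlation
#'   matrix over [trait_names()] with unit diagonal. Non-PSD matrices are
#'   rejected (never silently repaired), naming the offending eigenvalue.
#' @param trait_scales Data frame with columns `trait`, `link`, `mean`, `sd`
#'   giving each trait's location/scale on its link scale; defaults to
#'   [default_trait_scales()]. All `sd` must be > 0 (except the uniform
#'   `age` row).
#' @param age_range Two-element numeric, youngest and oldest age in years.
#' @param task_design List of per-task block/trial counts; see
#'   `default_task_design()` for fields and defaults (3 sentence blocks of 50
#'   trials; 2 quiet and 3 masked intensity tracks; 2 TFS tracks; 3 flanker
#'   blocks of 64 trials; 10 span lists).
#' @param sentence_practice_penalty Reduction of the per-word probability
#'   correct in sentence block 1 (practice effect), on the probability scale.
#' @param flanker_practice_penalty Additive inflation of block-1 log RTs.
#' @param sigma_intensity Logistic psychometric spread of the simulated
#'   observer in the intensity task, dB on the 10*log10(dI/I) scale.
#' @param sigma_tfs Logistic psychometric spread in the interaural-phase
#'   task, log10-degrees.
#' @param rt_sigma Trial-to-trial SD of log RT in the flanker task.
#' @param flanker_error_rate Probability that a flanker trial is answered
#'   incorrectly (independent of RT).
#' @param ssq_noise_sd SD of the rating noise added to the latent SSQ
#'   subscale means (ratings are clipped to [0, 10]).
#' @param object_modulation Optional additive modulation of the flanker
#'   effect in the same-object condition (log-RT units); default 0.
#' @param seed Optional default seed used by [simulate_cohort()] when no
#'   seed is supplied there.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 10)
#' cfg$n_subjects
cohort_config <- function(n_subjects = 50L,
                          trait_correlations = default_trait_correlations(),
                          trait_scales = default_trait_scales(),
                          age_range = c(18, 30),
                          task_design = default_task_design(),
                          sentence_practice_penalty = 0.10,
                          flanker_practice_penalty = 0.05,
                          sigma_intensity = 5,
                          sigma_tfs = 0.25,
                          rt_sigma = 0.15,
                          flanker_error_rate = 0.05,
                          ssq_noise_sd = 0.5,
                          object_modulation = 0,
                          seed = NULL) {
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  n_subjects <- as.integer(n_subjects)

  tn <- trait_names()
  if (!is.matrix(trait_correlations) ||
      !identical(dim(trait_correlations), c(13L, 13L))) {
    stop_cocktailr("`trait_correlations` must be a 13 x 13 matrix over trait_names().",
                   class = "cocktailr_config_error")
  }
  if (is.null(dimnames(trait_correlations))) {
    dimnames(trait_correlations) <- list(tn, tn)
  }
  if (!identical(rownames(trait_correlations), tn)) {
    stop_cocktailr("`trait_correlations` rows/columns must be named and ordered as trait_names().",
                   class = "cocktailr_config_error")
  }
  if (max(abs(trait_correlations - t(trait_correlations))) > 1e-10) {
    stop_cocktailr("`trait_correlations` must be symmetric.",
                   class = "cocktailr_config_error")
  }
  if (max(abs(diag(trait_correlations) - 1)) > 1e-10) {
    stop_cocktailr("`trait_correlations` must have a unit diagonal.",
                   class = "cocktailr_config_error")
  }
  if (max(abs(trait_correlations)) > 1 + 1e-10) {
    stop_cocktailr("Correlations must lie in [-1, 1].",
                   class = "cocktailr_config_error")
  }
  ev <- eigen(trait_correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_cocktailr(sprintf(
      "`trait_correlations` is not positive semi-definite: smallest eigenvalue is %.6g. No automatic repair is applied; supply a valid matrix.",
      min(ev)
    ), class = "cocktailr_config_error")
  }

  stopifnot(is.data.frame(trait_scales),
            all(c("trait", "link", "mean", "sd") %in% names(trait_scales)))
  trait_scales <- trait_scales[match(tn, trait_scales$trait), ]
  if (anyNA(trait_scales$trait)) {
    stop_cocktailr("`trait_scales` must contain one row per trait in trait_names().",
                   class = "cocktailr_config_error")
  }
  bad_sd <- trait_scales$trait[trait_scales$link != "uniform" &
                                 (is.na(trait_scales$sd) | trait_scales$sd <= 0)]
  if (length(bad_sd)) {
    stop_cocktailr(sprintf("Trait SDs must be > 0; offending: %s.",
                           paste(bad_sd, collapse = ", ")),
                   class = "cocktailr_config_error")
  }

  if (length(age_range) != 2L || !is.numeric(age_range) ||
      age_range[1] >= age_range[2]) {
    stop_cocktailr("`age_range` must be an increasing pair of ages.",
                   class = "cocktailr_config_error")
  }

  needed <- names(default_task_design())
  missing <- setdiff(needed, names(task_design))
  if (length(missing)) {
    stop_cocktailr(sprintf("`task_design` is missing fields: %s.",
                           paste(missing, collapse = ", ")),
                   class = "cocktailr_config_error")
  }
  counts <- unlist(task_design[setdiff(needed, "span_lengths")])
  if (any(!is.finite(counts)) || any(counts < 1)) {
    stop_cocktailr("All task_design block/trial counts must be >= 1.",
                   class = "cocktailr_config_error")
  }

  assert_scalar_number(sentence_practice_penalty, "sentence_practice_penalty", 0, 1)
  assert_scalar_number(flanker_practice_penalty, "flanker_practice_penalty", 0, 5)
  assert_scalar_number(sigma_intensity, "sigma_intensity", lower = 1e-12)
  assert_scalar_number(sigma_tfs, "sigma_tfs", lower = 1e-12)
  assert_scalar_number(rt_sigma, "rt_sigma", lower = 0)
  assert_scalar_number(flanker_error_rate, "flanker_error_rate", 0, 1)
  assert_scalar_number(ssq_noise_sd, "ssq_noise_sd", lower = 0)
  assert_scalar_number(object_modulation, "object_modulation", -5, 5)

  structure(
    list(
      n_subjects = n_subjects,
      trait_correlations = trait_correlations,
      trait_scales = tibble::as_tibble(trait_scales),
      age_range = as.numeric(age_range),
      task_design = task_design,
      sentence_practice_penalty = sentence_practice_penalty,
      flanker_practice_penalty = flanker_practice_penalty,
      sigma_intensity = sigma_intensity,
      sigma_tfs = sigma_tfs,
      rt_sigma = rt_sigma,
      flanker_error_rate = flanker_error_rate,
      ssq_noise_sd = ssq_noise_sd,
      object_modulation = object_modulation,
      seed = seed
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:", x$n_subjects, "  age range:",
      paste(x$age_range, collapse = "-"), "years\n")
  td <- x$task_design
  cat(sprintf("  sentence: %d blocks x %d trials; intensity: %d quiet + %d masked tracks; TFS: %d tracks\n",
              td$sentence_blocks, td$sentence_trials, td$dl_quiet_blocks,
              td$dl_masked_blocks, td$tfs_blocks))
  cat(sprintf("  flanker: %d blocks x %d trials; span: %d lists\n",
              td$flanker_blocks, 16L * td$flanker_reps,
              length(td$span_lengths) * td$span_reps))
  invisible(x)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Accepts a file holding any subset of the [cohort_config()] arguments
#' (scalar fields, `age_range`, `task_design`, and optionally
#' `trait_correlations` as a list of rows); everything is validated by
#' [cohort_config()], so invalid files fail before any simulation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) {
    stop_cocktailr(sprintf("Config file not found: %s", path),
                   class = "cocktailr_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) {
    stop_cocktailr("Config file must define a mapping of cohort_config() fields.",
                   class = "cocktailr_config_error")
  }
  known <- setdiff(names(formals(cohort_config)), "trait_scales")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_cocktailr(sprintf("Unknown config field(s): %s.",
                           paste(unknown, collapse = ", ")),
                   class = "cocktailr_config_error")
  }
  if (!is.null(raw$trait_correlations)) {
    m <- as.matrix(do.call(rbind, raw$trait_correlations))
    storage.mode(m) <- "double"
    dimnames(m) <- list(trait_names(), trait_names())
    raw$trait_correlations <- m
  }
  if (!is.null(raw$task_design)) {
    td <- default_task_design()
    td[names(raw$task_design)] <- raw$task_design
    raw$task_design <- td
  }
  do.call(cohort_config, raw)
}
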