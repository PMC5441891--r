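#' Simulate the multi-talker sentence identification task for one listener
#'
#' Each trial presents a five-word matrix sentence; every word is reported
#' correctly with the listener's latent per-word intelligibility,
#' independently across words and trials. In block 1 the probability is
#' reduced by the configured practice penalty (floored at the 0.1 guessing
#' rate of a ten-alternative word matrix), emulating the practice effect
#' typically seen in the first block.
#'
#' @param listener One row of a [generate_cohort()] tibble.
#' @param config A [cohort_config()] (block/trial counts and the practice
#'   penalty are read from it).
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `subject_id`, `task`
#'   ("sentence"), `block`, `trial`, and logical word-correctness flags
#'   `word1` ... `word5`.
#' @export
simulate_sentence_task <- function(listener, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  wi <- listener$word_intelligibility
  if (is.na(wi) || wi < 0.1 || wi > 1) {
    stop_cocktailr("`word_intelligibility` must lie in [0.1, 1].")
  }
  with_seed(seed, {
    td <- config$task_design
    nb <- td$sentence_blocks
    nt <- td$sentence_trials
    nw <- td$sentence_words
    p_block <- rep(wi, nb)
    p_block[1] <- max(0.1, wi - config$sentence_practice_penalty)
    n <- nb * nt
    block <- rep(seq_len(nb), each = nt)
    cols <- c(
      list(subject_id = rep(listener$subject_id, n),
           task = rep("sentence", n),
           block = block,
           trial = rep(seq_len(nt), nb)),
      setNames(
        lapply(seq_len(nw), function(w) runif(n) < p_block[block]),
        paste0("word", seq_len(nw))
      )
    )
    tibble::new_tibble(cols, nrow = n)
  })
}

#' Build a stochastic 2AFC responder for an adaptive track
#'
#' Returns a function mapping a stimulus level to a logical correct/incorrect
#' response, with P(correct) = 0.5 + 0.5 * F((x - theta) / sigma) where F is
#' the logistic CDF: guessing rate 0.5, P(correct) = 0.75 at `x = theta`.
#' Intensity tasks operate in dB on the 10*log10(dI/I) scale; the
#' interaural-phase task operates in log10-degrees (the responder takes the
#' level in degrees and transforms internally).
#'
#' @param listener One row of a cohort tibble.
#' @param task One of "intensity_quiet", "intensity_masked", "tfs".
#' @param config A [cohort_config()] supplying the psychometric spreads.
#' @return A function `(level) -> logical`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 1), seed = 1)
#' resp <- make_responder(coh[1, ], "intensity_quiet", cohort_config())
#' set.seed(1); resp(coh$dl_quiet_true[1] + 50)  # far above threshold
make_responder <- function(listener, task, config = cohort_config()) {
  task <- match.arg(task, c("intensity_quiet", "intensity_masked", "tfs"))
  if (task == "tfs") {
    theta <- log10(listener$ipd_threshold_true)
    sigma <- config$sigma_tfs
    trans <- log10
  } else {
    theta <- if (task == "intensity_quiet") listener$dl_quiet_true
             else listener$dl_masked_true
    sigma <- config$sigma_intensity
    trans <- identity
  }
  if (!is.finite(theta)) stop_cocktailr("Listener lacks the true threshold for this task.")
  function(level) {
    p <- 0.5 + 0.5 * plogis((trans(level) - theta) / sigma)
    runif(1L) < p
  }
}

#' Simulate the visual flanker task for one listener
#'
#' Trials cross distractor type (neutral / incompatible), object condition
#' (same / different), target type and target colour: 16 conditions, each
#' repeated `flanker_reps` times per block in random order (64 trials per
#' block at the default). Log RTs are Gaussian around the listener's base
#' log RT; incompatible trials add the latent flanker effect (optionally
#' modulated in the same-object condition), and block-1 trials add the
#' practice penalty. A configurable error rate marks trials incorrect.
#'
#' @inheritParams simulate_sentence_task
#' @return A tibble with one row per trial: `subject_id`, `task`
#'   ("flanker"), `block`, `trial`, `distractor`, `object`, `target`,
#'   `colour`, `rt_ms`, `correct`.
#' @export
simulate_flanker <- function(listener, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.finite(listener$base_log_rt)) {
    stop_cocktailr("`base_log_rt` must be finite.")
  }
  with_seed(seed, {
    td <- config$task_design
    conds <- tidyr::expand_grid(
      distractor = c("neutral", "incompatible"),
      object = c("same", "different"),
      target = c("dotted", "dashed"),
      colour = c("blue", "green")
    )
    per_block <- nrow(conds) * td$flanker_reps
    # each block presents every condition `flanker_reps` times in random order
    idx <- unlist(lapply(seq_len(td$flanker_blocks), function(b) {
      rep(seq_len(nrow(conds)), td$flanker_reps)[sample.int(per_block)]
    }))
    n <- td$flanker_blocks * per_block
    block <- rep(seq_len(td$flanker_blocks), each = per_block)
    distractor <- conds$distractor[idx]
    object <- conds$object[idx]
    mu <- listener$base_log_rt +
      (distractor == "incompatible") *
        (listener$flanker_effect_true +
           config$object_modulation * (object == "same")) +
      (block == 1L) * config$flanker_practice_penalty
    tibble::new_tibble(list(
      subject_id = rep(listener$subject_id, n),
      task = rep("flanker", n),
      block = block,
      trial = rep(seq_len(per_block), td$flanker_blocks),
      distractor = distractor,
      object = object,
      target = conds$target[idx],
      colour = conds$colour[idx],
      rt_ms = exp(mu + rnorm(n, 0, config$rt_sigma)),
      correct = runif(n) >= config$flanker_error_rate
    ), nrow = n)
  })
}

SPAN_CONSONANTS <- c("B", "D", "F", "G", "H", "J", "K", "L", "M", "N",
                     "P", "Q", "R", "S", "T", "W", "Z")

#' Simulate the sentence span task for one listener
#'
#' Presents two lists at each of the lengths 3-7 (10 lists, 50 consonants in
#' total at the default design) in random order. Each presented consonant is
#' recalled in its correct serial position with the listener's latent recall
#' probability; otherwise a different consonant is reported (responses always
#' have the presented length, as the task forces full-length answers).
#'
#' @inheritParams simulate_sentence_task
#' @return A tibble with one row per serial position: `subject_id`, `task`
#'   ("span"), `block` (list number), `trial` (serial position),
#'   `list_length`, `presented`, `recalled`.
#' @export
simulate_span_task <- function(listener, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  p <- listener$span_recall_prob
  if (is.na(p) || p < 0 || p > 1) {
    stop_cocktailr("`span_recall_prob` must lie in [0, 1].")
  }
  with_seed(seed, {
    td <- config$task_design
    lengths <- rep(td$span_lengths, td$span_reps)
    lengths <- lengths[sample.int(length(lengths))]
    presented <- unlist(lapply(lengths, function(len) sample(SPAN_CONSONANTS, len)))
    n <- length(presented)
    ok <- runif(n) < p
    recalled <- presented
    if (any(!ok)) {
      recalled[!ok] <- vapply(presented[!ok], function(ch) {
        sample(SPAN_CONSONANTS[SPAN_CONSONANTS != ch], 1L)
      }, character(1))
    }
    tibble::new_tibble(list(
      subject_id = rep(listener$subject_id, n),
      task = rep("span", n),
      block = rep(seq_along(lengths), lengths),
      trial = unlist(lapply(lengths, seq_len)),
      list_length = rep(lengths, lengths),
      presented = presented,
      recalled = recalled
    ), nrow = n)
  })
}

#' Simulate SSQ questionnaire subscale scores for one listener
#'
#' Each subscale score is the listener's latent subscale mean plus Gaussian
#' rating noise, clipped to the 0-10 response scale.
#'
#' @inheritParams simulate_sentence_task
#' @return A one-row tibble: `subject_id`, `ssq_speech`, `ssq_spatial`,
#'   `ssq_qualities`.
#' @export
simulate_ssq <- function(listener, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    noise <- rnorm(3L, 0, config$ssq_noise_sd)
    tibble::new_tibble(list(
      subject_id = listener$subject_id,
      ssq_speech = min(max(listener$ssq_speech_true + noise[1], 0), 10),
      ssq_spatial = min(max(listener$ssq_spatial_true + noise[2], 0), 10),
      ssq_qualities = min(max(listener$ssq_qualities_true + noise[3], 0), 10)
    ), nrow = 1L)
  })
}
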