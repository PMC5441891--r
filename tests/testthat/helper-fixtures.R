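# Shared fixtures: tiny configs, hand-built tracks and trial tables.

tiny_config <- function(n = 3L, ...) cohort_config(n_subjects = n, ...)

one_listener <- function(seed = 1L, ...) {
  generate_cohort(cohort_config(n_subjects = 1L, ...), seed = seed)[1, ]
}

# A latent correlation matrix with effects planted only on the two traits
# driving speech intelligibility; everything else mutually independent.
planted_correlations <- function(r = -0.65) {
  R <- diag(13)
  dimnames(R) <- list(trait_names(), trait_names())
  R["speech", "dl_elev"] <- R["dl_elev", "speech"] <- r
  R["speech", "tfs"] <- R["tfs", "speech"] <- r
  R
}

# Build an adaptive_track object directly from a reversal-level sequence
# (for estimator arithmetic that must be hand-checkable).
fake_track <- function(levels, task = "intensity_quiet",
                       terminated_by = "reversals") {
  spec <- staircase_spec(task)
  structure(
    list(
      spec = spec,
      trials = tibble::tibble(trial = seq_along(levels),
                              level = levels,
                              correct = rep(TRUE, length(levels))),
      reversals = tibble::tibble(reversal = seq_along(levels),
                                 trial = seq_along(levels),
                                 level = levels),
      terminated_by = terminated_by,
      valid = terminated_by == "reversals" || task == "tfs",
      reason = NA_character_
    ),
    class = "adaptive_track"
  )
}

# Sentence-trial table with exact per-block word-correct counts.
sentence_trials_exact <- function(block_props, n_trials = 50L,
                                  subject_id = 1L) {
  purrr::map_dfr(seq_along(block_props), function(b) {
    n_words <- n_trials * 5L
    n_ok <- round(block_props[b] * n_words)
    ok <- c(rep(TRUE, n_ok), rep(FALSE, n_words - n_ok))
    m <- matrix(ok, ncol = 5L)
    tibble::tibble(
      subject_id = subject_id, task = "sentence", block = b,
      trial = seq_len(n_trials),
      word1 = m[, 1], word2 = m[, 2], word3 = m[, 3],
      word4 = m[, 4], word5 = m[, 5]
    )
  })
}

# Flanker trials with fixed RTs per cell (blocks 2 and 3, both objects).
flanker_trials_fixed <- function(rt_neutral = 500, rt_incompatible = 550,
                                 n_per_cell = 4L, subject_id = 1L) {
  tidyr::expand_grid(
    block = 2:3,
    distractor = c("neutral", "incompatible"),
    object = c("same", "different"),
    trial = seq_len(n_per_cell)
  ) |>
    dplyr::mutate(
      subject_id = subject_id, task = "flanker",
      target = "dotted", colour = "blue",
      rt_ms = ifelse(.data$distractor == "neutral", rt_neutral,
                     rt_incompatible),
      correct = TRUE
    )
}

# Independent ICC(A,k) oracle from a two-way fixed-effects ANOVA table.
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    value = as.vector(m),
    row = factor(rep(seq_len(n), k)),
    col = factor(rep(seq_len(k), each = n))
  )
  ms <- anova(lm(value ~ row + col, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Centred orthonormal design: columns mutually orthogonal, orthogonal to the
# intercept, unit length (so sample correlations are exactly zero).
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1), drop = FALSE]
  colnames(Q) <- paste0("x", seq_len(p))
  Q
}
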