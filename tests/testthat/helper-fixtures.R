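# Small, fully code-built fixtures shared across test files.

# Hand-built 3-trial sequence: dependent condition, gain cues, forced dark
# choices, transitions heist/heist/neutral.
hand_three_trials <- function() {
  tibble::tibble(
    subject = 1L, session = 1L, block = 1L, condition = "dependent",
    context = 1L, trial = 1:3, trial_type = "forced", valence = "gain",
    door_presented = "dark", choice = "dark",
    state = c("heist", "heist", "neutral"), outcome = c(1L, 1L, 0L),
    p_true = 0.8
  )
}

# A trial table with randomly filled choices/states (not model-generated),
# for likelihood-mode equivalence checks.
random_filled_table <- function(n_sessions = 2L, trials_per_block = 16L,
                                forced = 12L, free = 4L) {
  cfg <- task_config("fmri", n_sessions = n_sessions,
                     trials_per_block = trials_per_block,
                     forced_per_block = forced, free_per_block = free)
  tt <- generate_trial_table(cfg)
  free_idx <- tt$trial_type == "free"
  tt$choice <- tt$door_presented
  tt$choice[free_idx] <- sample(c("dark", "light"), sum(free_idx),
                                replace = TRUE)
  step <- sample_step(tt$choice, tt$p_true, tt$valence)
  tt$state <- step$state
  tt$outcome <- step$outcome
  tt
}

# 9-trial consistency fixture: the 8 eligible trials split into 4 with a
# positive and 4 with a negative previous outcome, with 3/4 and 1/4
# consistent choices respectively.
consistency_fixture <- function() {
  tibble::tibble(
    subject = 1L, session = 1L, block = 1L, condition = "dependent",
    context = 1L, trial = 1:9, trial_type = "free",
    valence = c("gain", "gain", "gain", "loss", "gain", "loss", "gain",
                "gain", "loss"),
    door_presented = "dark",
    choice = c("dark", "dark", "dark", "light", "light", "light", "dark",
               "dark", "light"),
    state = c("heist", "heist", "heist", "neutral", "neutral", "heist",
              "neutral", "neutral", "neutral"),
    outcome = c(1L, 1L, 1L, 0L, 0L, -1L, 0L, 0L, 0L),
    p_true = 0.8
  )
}

# Quick flexible-agent cohort at the reference group parameters.
simulate_pool_cohort <- function(n_subjects, variant = "flexible",
                                 config = task_config("fmri"),
                                 pool = NULL) {
  pool <- if (is.null(pool)) sample_params_pool(n_subjects, variant) else pool
  lapply(seq_len(n_subjects), function(i) {
    row <- pool[((i - 1L) %% nrow(pool)) + 1L, ]
    simulate_subject(model_params(row$alpha, row$beta, row$w), variant,
                     config, subject = i)
  })
}
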