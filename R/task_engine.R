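#' Task configuration for the heist task
#'
#' The heist task is a two-stage planning task. On each trial one of two doors
#' (dark/light) is presented in one of four visual contexts ("gems"). The
#' chosen door leads to a "heist" state with probability `p` (dark door) or
#' `1 - p` (light door), and to a "neutral" state otherwise. A cue shown
#' before choice signals whether reaching the heist state yields a gain (+1)
#' or a loss (-1); the neutral state always yields 0. `p` alternates between
#' two levels with a fixed per-trial hazard. Each block pairs two contexts:
#' in *dependent* blocks both contexts share one transition schedule, in
#' *independent* blocks the two schedules are generated independently.
#'
#' Two standard designs are provided. The `fmri` design has 5 sessions of two
#' 32-trial blocks (one block per condition, order counterbalanced), 24 forced
#' and 8 free-choice trials per block, 320 trials total. The `pilot` design
#' has 8 blocks of 60 trials, all free choice (480 trials total).
#'
#' @param design `"fmri"` or `"pilot"`; fills every other argument's default.
#' @param n_sessions Number of sessions; each session holds one dependent and
#'   one independent block.
#' @param trials_per_block,forced_per_block,free_per_block Per-block trial
#'   counts; forced + free must equal the block length.
#' @param p_levels The two transition-probability levels the schedule
#'   alternates between.
#' @param hazard Per-trial probability that the schedule switches level.
#'
#' @return A list of class `heist_task_config`.
#' @examples
#' cfg <- task_config("fmri")
#' cfg$trials_per_block
#' @export
task_config <- function(design = c("fmri", "pilot"),
                        n_sessions = NULL,
                        trials_per_block = NULL,
                        forced_per_block = NULL,
                        free_per_block = NULL,
                        p_levels = c(0.2, 0.8),
                        hazard = 0.1) {
  design <- match.arg(design)
  defaults <- switch(design,
    fmri  = list(n_sessions = 5L, trials_per_block = 32L,
                 forced_per_block = 24L, free_per_block = 8L),
    pilot = list(n_sessions = 4L, trials_per_block = 60L,
                 forced_per_block = 0L, free_per_block = 60L)
  )
  n_sessions <- as.integer(n_sessions %||% defaults$n_sessions)
  trials_per_block <- as.integer(trials_per_block %||% defaults$trials_per_block)
  forced_per_block <- as.integer(forced_per_block %||% defaults$forced_per_block)
  free_per_block <- as.integer(free_per_block %||% defaults$free_per_block)

  if (forced_per_block + free_per_block != trials_per_block) {
    abort("forced_per_block + free_per_block must equal trials_per_block")
  }
  if (trials_per_block %% 2L != 0L) {
    abort("trials_per_block must be even (two interleaved contexts per block)")
  }
  check_probability(hazard, "hazard")
  if (length(p_levels) != 2L || anyDuplicated(p_levels) ||
      any(p_levels < 0) || any(p_levels > 1)) {
    abort("p_levels must be two distinct probabilities")
  }

  structure(
    list(design = design, n_sessions = n_sessions,
         blocks_per_session = 2L,
         trials_per_block = trials_per_block,
         forced_per_block = forced_per_block,
         free_per_block = free_per_block,
         p_levels = as.numeric(p_levels), hazard = hazard,
         contexts = list(dependent = c(1L, 2L), independent = c(3L, 4L))),
    class = "heist_task_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

#' Generate transition-probability schedules for a block
#'
#' Each context's schedule starts at a level drawn uniformly from `levels`
#' and switches to the other level with probability `hazard` on every trial.
#' With `yoked = TRUE` (dependent blocks) a single schedule is drawn and
#' copied to both contexts; with `yoked = FALSE` the two schedules are
#' independent draws.
#'
#' @param n_trials Number of trials in the block.
#' @param hazard Per-trial switch probability.
#' @param levels The two probability levels.
#' @param yoked Share one schedule across both contexts?
#' @return A tibble with columns `trial`, `p_a`, `p_b` (the per-trial level
#'   for the block's two contexts).
#' @examples
#' set.seed(1)
#' generate_transition_schedule(8, hazard = 0.1, yoked = TRUE)
#' @export
generate_transition_schedule <- function(n_trials, hazard = 0.1,
                                         levels = c(0.2, 0.8), yoked = TRUE) {
  if (n_trials < 1L) abort("n_trials must be >= 1")
  check_probability(hazard, "hazard")
  draw_one <- function() {
    lev <- numeric(n_trials)
    cur <- sample(levels, 1L)
    for (t in seq_len(n_trials)) {
      if (t > 1L && runif(1) < hazard) cur <- levels[levels != cur]
      lev[t] <- cur
    }
    lev
  }
  p_a <- draw_one()
  p_b <- if (yoked) p_a else draw_one()
  tibble::tibble(trial = seq_len(n_trials), p_a = p_a, p_b = p_b)
}

#' Generate the design of a subject's trial table
#'
#' Lays out sessions, blocks, conditions, contexts, trial types, valence cues,
#' presented doors and the true transition schedules. Behavioural columns
#' (`choice`, `state`, `outcome`) are left `NA`; fill them with
#' [simulate_subject()] or by ingesting real choices.
#'
#' Within each session the dependent/independent block order is decided by a
#' coin flip. Within a block the two contexts are randomly interleaved with
#' equal counts, valence and presented door are fair coins per trial, and
#' forced/free labels are randomly placed with the configured counts. In a
#' dependent block both contexts share one schedule; in an independent block
#' the two schedules are drawn independently. Each block's schedule starts at
#' a uniformly drawn level.
#'
#' @param config A [task_config()].
#' @param subject Subject identifier stored in the `subject` column.
#' @return A tibble with one row per trial (a trial table), columns:
#'   `subject`, `session`, `block`, `condition`, `context`, `trial`,
#'   `trial_type`, `valence`, `door_presented`, `choice`, `state`, `outcome`,
#'   `p_true`.
#' @examples
#' set.seed(1)
#' tt <- generate_trial_table(task_config("fmri"))
#' nrow(tt)
#' @export
generate_trial_table <- function(config = task_config("fmri"), subject = 1L) {
  stopifnot(inherits(config, "heist_task_config"))
  n_b <- config$trials_per_block

  one_block <- function(session, block_in_session, condition) {
    ctxs <- config$contexts[[condition]]
    context <- sample(rep(ctxs, each = n_b / 2L))
    trial_type <- sample(rep(c("forced", "free"),
                             c(config$forced_per_block, config$free_per_block)))
    sched <- generate_transition_schedule(
      n_b, hazard = config$hazard, levels = config$p_levels,
      yoked = (condition == "dependent")
    )
    p_true <- ifelse(context == ctxs[1L], sched$p_a, sched$p_b)
    tibble::tibble(
      subject = subject, session = session, block = block_in_session,
      condition = condition, context = context,
      trial_type = trial_type,
      valence = sample(c("gain", "loss"), n_b, replace = TRUE),
      door_presented = sample(c("dark", "light"), n_b, replace = TRUE),
      choice = NA_character_, state = NA_character_,
      outcome = NA_integer_, p_true = p_true
    )
  }

  tab <- purrr::map_dfr(seq_len(config$n_sessions), function(s) {
    first_dep <- runif(1) < 0.5
    conds <- if (first_dep) c("dependent", "independent") else
      c("independent", "dependent")
    dplyr::bind_rows(one_block(s, 1L, conds[1L]), one_block(s, 2L, conds[2L]))
  })
  tab$trial <- seq_len(nrow(tab))
  dplyr::relocate(tab, "trial", .after = "context")
}

#' Sample the second-stage state and outcome for chosen doors
#'
#' The dark door transitions to the heist state with probability `p_true`,
#' the light door with probability `1 - p_true`. The outcome is +1 in the
#' heist state on gain trials, -1 in the heist state on loss trials, and 0 in
#' the neutral state. Missed choices yield `NA` state and outcome.
#'
#' @param choice Character vector, `"dark"`, `"light"` or `"missed"`.
#' @param p_true Per-trial probability that the dark door leads to heist.
#' @param valence `"gain"` or `"loss"` per trial.
#' @return A tibble with columns `state` and `outcome`.
#' @examples
#' set.seed(1)
#' sample_step(c("dark", "light"), c(0.8, 0.8), c("gain", "loss"))
#' @export
sample_step <- function(choice, p_true, valence) {
  stopifnot(length(choice) == length(p_true), length(choice) == length(valence))
  p_heist <- ifelse(choice == "dark", p_true, 1 - p_true)
  state <- ifelse(choice == "missed", NA_character_,
                  ifelse(runif(length(choice)) < p_heist, "heist", "neutral"))
  outcome <- dplyr::case_when(
    is.na(state) ~ NA_integer_,
    state == "neutral" ~ 0L,
    valence == "gain" ~ 1L,
    TRUE ~ -1L
  )
  tibble::tibble(state = state, outcome = outcome)
}
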