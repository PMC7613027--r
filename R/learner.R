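#' Dual-learner model parameters
#'
#' The model tracks the dark-door-to-heist transition probability with two
#' learners: a context-independent estimate (one per condition's context
#' pair) and a context-specific estimate (one per context). At choice the two
#' are mixed into a single estimate `p_hat` by a weight `w`; after feedback a
#' state prediction error updates both, with the same weighting and a
#' learning rate `alpha`. Choices follow a softmax with inverse temperature
#' `beta` over the valence-signed action values.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Softmax inverse temperature, >= 0.
#' @param w Mixing weight in \[0, 1\] placed on the context-independent
#'   learner (in the dependent condition; the flexible variant uses `1 - w`
#'   in the independent condition).
#' @return A list of class `heist_model_params`.
#' @examples
#' model_params(0.5, 1, 0.8)
#' @export
model_params <- function(alpha, beta, w) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (!is.numeric(beta) || beta < 0) abort("beta must be >= 0")
  if (!is.numeric(w) || w < 0 || w > 1) abort("w must be in [0, 1]")
  structure(list(alpha = alpha, beta = beta, w = w),
            class = "heist_model_params")
}

#' Initial belief state
#'
#' All transition estimates start at 0.5 and carry over between blocks (no
#' reset at block boundaries).
#'
#' @return A list with `p_specific` (one entry per context, 1..4) and
#'   `p_independent` (one entry per condition).
#' @export
belief_state <- function() {
  list(
    p_specific = c(`1` = 0.5, `2` = 0.5, `3` = 0.5, `4` = 0.5),
    p_independent = c(dependent = 0.5, independent = 0.5)
  )
}

effective_weight <- function(w, condition, variant) {
  if (variant == "flexible" && condition == "independent") 1 - w else w
}

#' Combined transition estimate
#'
#' Mixes the context-independent and context-specific beliefs:
#' `p_hat = w_eff * p_independent + (1 - w_eff) * p_specific[context]`, where
#' `w_eff = w` except for the flexible variant in the independent condition,
#' where `w_eff = 1 - w`.
#'
#' @param beliefs A [belief_state()].
#' @param params A [model_params()].
#' @param condition `"dependent"` or `"independent"`.
#' @param context Context id (must belong to `condition`).
#' @param variant `"fixed"` or `"flexible"`.
#' @return The scalar combined estimate `p_hat`.
#' @examples
#' b <- belief_state()
#' b$p_independent["dependent"] <- 0.7
#' combined_estimate(b, model_params(0.5, 1, 0.8), "dependent", 1, "fixed")
#' @export
combined_estimate <- function(beliefs, params, condition, context,
                              variant = c("fixed", "flexible")) {
  variant <- match.arg(variant)
  check_context_condition(context, condition)
  w_eff <- effective_weight(params$w, condition, variant)
  unname(w_eff * beliefs$p_independent[[condition]] +
           (1 - w_eff) * beliefs$p_specific[[as.character(context)]])
}

check_context_condition <- function(context, condition) {
  ok <- (condition == "dependent" && context %in% c(1L, 2L)) ||
    (condition == "independent" && context %in% c(3L, 4L))
  if (!ok) abort(sprintf("context %s does not belong to the %s condition",
                         context, condition))
  invisible(TRUE)
}

#' Action values and choice probability
#'
#' `Q_dark = r * p_hat`, `Q_light = r * (1 - p_hat)` with `r = +1` on gain
#' and `-1` on loss trials; the dark door is chosen with probability
#' `1 / (1 + exp(beta * (Q_light - Q_dark)))`.
#'
#' @param p_hat Combined transition estimate(s).
#' @param valence `"gain"` or `"loss"`.
#' @param beta Softmax inverse temperature.
#' @return A tibble with `q_dark`, `q_light`, `choice_prob_dark`.
#' @examples
#' action_values(0.61, "gain", 1)
#' @export
action_values <- function(p_hat, valence, beta) {
  r <- ifelse(valence == "gain", 1, -1)
  q_dark <- r * p_hat
  q_light <- r * (1 - p_hat)
  tibble::tibble(
    q_dark = q_dark, q_light = q_light,
    choice_prob_dark = 1 / (1 + exp(beta * (q_light - q_dark)))
  )
}

#' State prediction error
#'
#' `delta = x - p_hat`, with `x = 1` when the observed transition is the one
#' the dark-door probability tracks (dark to heist, or light to neutral) and
#' `x = 0` otherwise.
#'
#' @param choice `"dark"` or `"light"` (missed trials have no update).
#' @param state `"heist"` or `"neutral"`.
#' @param p_hat The combined estimate used at choice.
#' @return The signed prediction error.
#' @examples
#' state_prediction_error("dark", "heist", 0.5)
#' @export
state_prediction_error <- function(choice, state, p_hat) {
  if (any(choice == "missed")) abort("missed trials carry no prediction error")
  x <- as.numeric((choice == "dark" & state == "heist") |
                    (choice == "light" & state == "neutral"))
  x - p_hat
}

#' Update beliefs after a transition
#'
#' `p_independent += w_eff * alpha * delta` and
#' `p_specific[context] += (1 - w_eff) * alpha * delta`, each clamped to
#' \[0, 1\]; `w_eff` is the same effective weight used in
#' [combined_estimate()]. Other entries are untouched.
#'
#' @inheritParams combined_estimate
#' @param delta State prediction error from the same trial's `p_hat`.
#' @return The updated belief state.
#' @export
update_beliefs <- function(beliefs, delta, params, condition, context,
                           variant = c("fixed", "flexible")) {
  variant <- match.arg(variant)
  check_context_condition(context, condition)
  w_eff <- effective_weight(params$w, condition, variant)
  key <- as.character(context)
  beliefs$p_independent[[condition]] <-
    min(1, max(0, beliefs$p_independent[[condition]] + w_eff * params$alpha * delta))
  beliefs$p_specific[[key]] <-
    min(1, max(0, beliefs$p_specific[[key]] + (1 - w_eff) * params$alpha * delta))
  beliefs
}

# ---- integer encodings shared with the C++ core ----

encode_trials <- function(trials, require_choices = FALSE) {
  needed <- c("condition", "context", "valence", "trial_type",
              "door_presented", "p_true")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(paste0("trial table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (is.unsorted(trials$trial)) abort("trials must be ordered by trial index")
  ch <- trials$choice
  st <- trials$state
  if (require_choices && (anyNA(ch) || anyNA(st[!is.na(ch) & ch != "missed"]))) {
    abort("likelihood mode requires filled choice and state columns")
  }
  list(
    condition = match(trials$condition, c("dependent", "independent")),
    context = as.integer(trials$context),
    valence = match(trials$valence, c("gain", "loss")),
    trial_type = match(trials$trial_type, c("forced", "free")),
    choice = ifelse(is.na(ch) | ch == "missed", 0L,
                    match(ch, c("dark", "light"))),
    state = ifelse(is.na(st), 0L, match(st, c("heist", "neutral"))),
    door = match(trials$door_presented, c("dark", "light")),
    p_true = as.numeric(trials$p_true)
  )
}

#' Run the dual-learner model over a trial table
#'
#' Sequentially applies [combined_estimate()], choice (observed in
#' `likelihood` mode, sampled in `simulate` mode), the state transition
#' (sampled from `p_true` in `simulate` mode), [state_prediction_error()] and
#' [update_beliefs()]. Beliefs update on every non-missed trial (forced and
#' free); the log likelihood sums only over free, non-missed trials.
#'
#' @param trials A trial table (see [generate_trial_table()]), time-ordered.
#' @param params A [model_params()].
#' @param variant `"fixed"` or `"flexible"`.
#' @param mode `"likelihood"` (choices observed) or `"simulate"` (choices and
#'   transitions generated; forced-trial choices take the presented door,
#'   which the generator draws as a fair coin).
#' @return A tibble aligned with `trials`: `p_hat`, `q_dark`, `q_light`,
#'   `choice_prob_dark`, `delta`, `abs_delta`, `loglik_contribution`, and in
#'   simulate mode `choice`, `state`, `outcome`. The summed log likelihood is
#'   attached as attribute `loglik`.
#' @examples
#' set.seed(1)
#' tt <- generate_trial_table(task_config("fmri"))
#' traj <- run_model(tt, model_params(0.5, 1, 0.8), "flexible", mode = "simulate")
#' attr(traj, "loglik")
#' @export
run_model <- function(trials, params, variant = c("fixed", "flexible"),
                      mode = c("likelihood", "simulate")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  stopifnot(inherits(params, "heist_model_params"))
  enc <- encode_trials(trials, require_choices = (mode == "likelihood"))
  res <- model_pass_cpp(enc$condition, enc$context, enc$valence,
                        enc$trial_type, enc$choice, enc$state, enc$door,
                        enc$p_true, params$alpha, params$beta, params$w,
                        flexible = (variant == "flexible"),
                        simulate = (mode == "simulate"), trajectory = TRUE)
  out <- tibble::tibble(
    p_hat = res$p_hat, q_dark = res$q_dark, q_light = res$q_light,
    choice_prob_dark = res$choice_prob_dark, delta = res$delta,
    abs_delta = abs(res$delta), loglik_contribution = res$loglik_contribution
  )
  if (mode == "simulate") {
    out$choice <- c("dark", "light")[res$choice]
    out$state <- c("heist", "neutral")[res$state]
    out$outcome <- res$outcome
  }
  attr(out, "loglik") <- res$loglik
  out
}

#' Simulate a full synthetic subject
#'
#' Generates a fresh trial table from `config` and lets an agent with the
#' given parameters play it, returning the table with `choice`, `state` and
#' `outcome` filled and the model trajectory columns appended.
#'
#' @inheritParams run_model
#' @param config A [task_config()].
#' @param subject Subject id stored in the table.
#' @return A tibble: trial table columns plus `p_hat`, `q_dark`, `q_light`,
#'   `choice_prob_dark`, `delta`, `abs_delta`, `loglik_contribution`.
#' @examples
#' set.seed(1)
#' sub <- simulate_subject(model_params(0.5, 2, 0.85), "flexible")
#' table(sub$condition, sub$state)
#' @export
simulate_subject <- function(params, variant = c("fixed", "flexible"),
                             config = task_config("fmri"), subject = 1L) {
  variant <- match.arg(variant)
  trials <- generate_trial_table(config, subject = subject)
  traj <- run_model(trials, params, variant, mode = "simulate")
  trials$choice <- traj$choice
  trials$state <- traj$state
  trials$outcome <- traj$outcome
  out <- dplyr::bind_cols(
    trials,
    traj[c("p_hat", "q_dark", "q_light", "choice_prob_dark", "delta",
           "abs_delta", "loglik_contribution")]
  )
  attr(out, "loglik") <- attr(traj, "loglik")
  out
}

#' Log likelihood of observed choices under the dual-learner model
#'
#' Hot path used by the hierarchical fit: returns only the summed log
#' likelihood over free, non-missed trials.
#'
#' @inheritParams run_model
#' @return A single numeric log likelihood.
#' @export
model_loglik <- function(trials, params, variant = c("fixed", "flexible")) {
  variant <- match.arg(variant)
  enc <- encode_trials(trials, require_choices = TRUE)
  -model_negloglik_cpp(enc$condition, enc$context, enc$valence,
                       enc$trial_type, enc$choice, enc$state,
                       params$alpha, params$beta, params$w,
                       flexible = (variant == "flexible"))
}
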