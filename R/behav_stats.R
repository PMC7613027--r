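#' Lagged transition-evidence regressors
#'
#' For each free, non-missed trial, codes the transition evidence received
#' 1..`n_lags` trials back. On a gain trial, a past dark-door transition to
#' the heist state (or light-door transition to neutral) is evidence `+1` for
#' picking the dark door now; transitions the other way are `-1`. The coding
#' is reversed when the current trial is a loss trial. Each lag is routed to
#' a `Same` or `Other` column according to whether the past trial shared the
#' current trial's context; the unused column (and lags whose source trial is
#' missed or falls outside the current block) are 0. Source trials may be
#' forced or free.
#'
#' @param trials A trial table with filled `choice`/`state`, time-ordered
#'   within subject. May contain several subjects.
#' @param n_lags Number of lags (default 5).
#' @return A tibble (class `heist_evidence`) with one row per free non-missed
#'   trial: `subject`, `trial`, `condition`, `context`, `response` (dark = 1,
#'   light = 0), `Condition` (+1 dependent, -1 independent), the lag columns
#'   `oneBackSame` ... `fiveBackOther`, and `differential_evidence`.
#' @examples
#' set.seed(1)
#' sub <- simulate_subject(model_params(0.5, 2, 0.85), "flexible")
#' em <- build_history_regressors(sub)
#' names(em)
#' @export
build_history_regressors <- function(trials, n_lags = 5L) {
  lag_names <- c("one", "two", "three", "four", "five",
                 "six", "seven", "eight", "nine", "ten")[seq_len(n_lags)]
  out <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(~ history_one_subject(.x, n_lags, lag_names)) |>
    dplyr::ungroup()
  same_cols <- paste0(lag_names, "BackSame")
  other_cols <- paste0(lag_names, "BackOther")
  out$differential_evidence <-
    rowMeans(out[same_cols]) - rowMeans(out[other_cols])
  class(out) <- c("heist_evidence", class(out))
  attr(out, "n_lags") <- n_lags
  out
}

history_one_subject <- function(df, n_lags, lag_names) {
  if (is.unsorted(df$trial)) abort("trials must be time-ordered within subject")
  n <- nrow(df)
  # evidence sign of the *source* trial in the gain frame: +1 when the
  # transition supports picking the dark door on a later gain trial
  x <- dplyr::case_when(
    is.na(df$choice) | df$choice == "missed" | is.na(df$state) ~ NA_real_,
    (df$choice == "dark") == (df$state == "heist") ~ 1,
    TRUE ~ -1
  )
  block_id <- paste(df$session, df$block)
  keep <- which(df$trial_type == "free" & !is.na(df$choice) &
                  df$choice != "missed")
  same <- matrix(0, n, n_lags)
  other <- matrix(0, n, n_lags)
  for (t in keep) {
    sign_cur <- if (df$valence[t] == "gain") 1 else -1
    for (l in seq_len(n_lags)) {
      s <- t - l
      if (s < 1L || block_id[s] != block_id[t] || is.na(x[s])) next
      ev <- sign_cur * x[s]
      if (df$context[s] == df$context[t]) same[t, l] <- ev else other[t, l] <- ev
    }
  }
  res <- tibble::tibble(
    trial = df$trial[keep],
    condition = df$condition[keep],
    context = df$context[keep],
    response = as.integer(df$choice[keep] == "dark"),
    Condition = ifelse(df$condition[keep] == "dependent", 1, -1)
  )
  for (l in seq_len(n_lags)) {
    res[[paste0(lag_names[l], "BackSame")]] <- same[keep, l]
    res[[paste0(lag_names[l], "BackOther")]] <- other[keep, l]
  }
  res
}

#' Differential evidence score
#'
#' Mean of the same-context lag columns minus the mean of the other-context
#' lag columns; positive values indicate a preference for evidence received
#' in the current trial's own context.
#'
#' @param em An evidence matrix from [build_history_regressors()].
#' @return A numeric vector, one score per row.
#' @export
differential_evidence <- function(em) {
  n_lags <- attr(em, "n_lags") %||% 5L
  lag_names <- c("one", "two", "three", "four", "five")[seq_len(n_lags)]
  rowMeans(em[paste0(lag_names, "BackSame")]) -
    rowMeans(em[paste0(lag_names, "BackOther")])
}

#' Fit a choice-history logistic regression
#'
#' Two model specifications are supported. `"ten_lag"` regresses the recoded
#' response on the 10 lagged evidence columns (fit this separately per
#' condition, as in the condition-wise analysis). `"differential_interaction"`
#' regresses the response on `differential_evidence * Condition`
#' (+1 dependent, -1 independent).
#'
#' Backends: `"glmer"` fits a mixed-effects logistic regression with all
#' regressors and the intercept as (diagonal-covariance) random effects
#' across subjects; `"glm_cluster"` fits a fixed-effects logistic regression
#' with cluster-robust (by subject) standard errors, a fast fallback for
#' simulated cohorts where the fully crossed random-effects model is often
#' singular.
#'
#' @param em An evidence matrix (filter to one condition for `"ten_lag"`).
#' @param spec `"ten_lag"` or `"differential_interaction"`.
#' @param backend `"glm_cluster"` or `"glmer"`.
#' @return A tibble of class `heist_coeftab` with columns `term`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high`, `p_value` (95% CI =
#'   estimate +/- 1.96 SE). Attributes: `backend`, `spec`, `singular`.
#' @export
fit_choice_history_model <- function(em,
                                     spec = c("ten_lag", "differential_interaction"),
                                     backend = c("glm_cluster", "glmer")) {
  spec <- match.arg(spec)
  backend <- match.arg(backend)
  if (nrow(em) == 0L) abort("empty evidence matrix")
  n_lags <- attr(em, "n_lags") %||% 5L
  lag_names <- c("one", "two", "three", "four", "five")[seq_len(n_lags)]
  terms <- switch(spec,
    ten_lag = c(paste0(lag_names, "BackSame"), paste0(lag_names, "BackOther")),
    differential_interaction = c("differential_evidence", "Condition",
                                 "differential_evidence:Condition")
  )
  rhs <- paste(terms, collapse = " + ")
  singular <- FALSE
  if (backend == "glmer") {
    fml <- stats::as.formula(
      paste0("response ~ ", rhs, " + (1 + ", rhs, " || subject)"))
    fit <- lme4::glmer(fml, data = em, family = binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
    singular <- lme4::isSingular(fit)
    if (singular) warn("random-effects fit is singular; interpret with care")
    cf <- summary(fit)$coefficients
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]; p <- cf[, "Pr(>|z|)"]
    term <- rownames(cf)
  } else {
    fml <- stats::as.formula(paste0("response ~ ", rhs))
    fit <- glm(fml, data = em, family = binomial())
    if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)) {
      singular <- TRUE
      warn("possible separation in fixed-effects logistic fit")
    }
    vc <- sandwich::vcovCL(fit, cluster = em$subject)
    ct <- lmtest::coeftest(fit, vcov. = vc)
    est <- ct[, "Estimate"]; se <- ct[, "Std. Error"]; p <- ct[, "Pr(>|z|)"]
    term <- rownames(ct)
  }
  out <- tibble::tibble(
    term = term, estimate = unname(est), std_error = unname(se),
    conf_low = unname(est - 1.96 * se), conf_high = unname(est + 1.96 * se),
    p_value = unname(p)
  )
  structure(out, class = c("heist_coeftab", class(out)),
            backend = backend, spec = spec, singular = singular)
}

#' Simulate cohorts of agents and summarise their history regressions
#'
#' For each simulation, `n_agents` virtual participants play a fresh task
#' (parameters resampled with replacement from `param_pool`), their choices
#' are recoded into lagged evidence regressors, and the ten-lag model is fit
#' separately per condition. Returns the fixed-effect estimates per
#' simulation, condition and term; average over simulations to obtain the
#' cohort-level pattern.
#'
#' @param n_sims Number of simulated groups.
#' @param variant Model variant the agents use.
#' @param param_pool Tibble with columns `alpha`, `beta`, `w`.
#' @param config A [task_config()].
#' @param n_agents Agents per simulated group.
#' @param backend Passed to [fit_choice_history_model()].
#' @return A tibble: `sim`, `condition`, `term`, `estimate`, `std_error`.
#' @export
simulate_cohorts <- function(n_sims, variant = c("flexible", "fixed"),
                             param_pool = sample_params_pool(29, variant),
                             config = task_config("fmri"), n_agents = 29L,
                             backend = "glm_cluster") {
  variant <- match.arg(variant)
  if (n_sims == 0L) {
    return(tibble::tibble(sim = integer(), condition = character(),
                          term = character(), estimate = numeric(),
                          std_error = numeric()))
  }
  if (nrow(param_pool) == 0L) abort("param_pool must be non-empty")
  purrr::map_dfr(seq_len(n_sims), function(s) {
    em <- simulate_group_evidence(n_agents, variant, param_pool, config)
    purrr::map_dfr(c("dependent", "independent"), function(cond) {
      sub <- em[em$condition == cond, ]
      ct <- fit_choice_history_model(sub, spec = "ten_lag", backend = backend)
      tibble::tibble(sim = s, condition = cond, term = ct$term,
                     estimate = ct$estimate, std_error = ct$std_error)
    })
  })
}

#' Simulate one group of agents and build its evidence matrix
#'
#' Resamples parameter sets from `param_pool` with replacement, lets each
#' agent play a fresh task, and returns the stacked lagged-evidence matrix
#' for the whole group.
#'
#' @inheritParams simulate_cohorts
#' @param n_agents Number of agents.
#' @return An evidence matrix (see [build_history_regressors()]).
#' @export
simulate_group_evidence <- function(n_agents, variant, param_pool, config) {
  rows <- sample(nrow(param_pool), n_agents, replace = TRUE)
  agents <- purrr::map_dfr(seq_len(n_agents), function(i) {
    pp <- param_pool[rows[i], ]
    simulate_subject(model_params(pp$alpha, pp$beta, pp$w), variant,
                     config, subject = i)
  })
  build_history_regressors(agents)
}

#' Agent-based permutation null for the evidence-by-condition interaction
#'
#' Simulates groups of agents under the fixed model (no reversal of `w`
#' between conditions) with `w` drawn uniformly on (0, 1) per agent and
#' `alpha`, `beta` resampled from `fixed_pool`. For each group the
#' `differential_evidence x Condition` interaction is estimated; the
#' collection of estimates forms a null distribution for agents that do not
#' adapt information integration between conditions.
#'
#' @param n_groups Number of simulated groups (the reference procedure uses
#'   500).
#' @param n_agents Agents per group.
#' @param fixed_pool Tibble with columns `alpha`, `beta`.
#' @param config A [task_config()].
#' @param observed Optional observed interaction estimate to score against
#'   the null.
#' @param backend Passed to [fit_choice_history_model()].
#' @return A list of class `heist_permnull`: `null_estimates`, `range95`
#'   (2.5% and 97.5% quantiles), and if `observed` was given, `observed` and
#'   the two-sided empirical `p_value` (share of null draws at least as
#'   extreme in absolute value, with the +1 continuity correction).
#' @export
permutation_null <- function(n_groups = 500L, n_agents = 29L,
                             fixed_pool = sample_params_pool(29, "fixed"),
                             config = task_config("fmri"), observed = NULL,
                             backend = "glm_cluster") {
  if (n_groups < 1L) abort("n_groups must be >= 1")
  est <- purrr::map_dbl(seq_len(n_groups), function(g) {
    pool <- tibble::tibble(
      alpha = sample(fixed_pool$alpha, n_agents, replace = TRUE),
      beta = sample(fixed_pool$beta, n_agents, replace = TRUE),
      w = runif(n_agents)
    )
    em <- simulate_group_evidence(n_agents, "fixed", pool, config)
    ct <- fit_choice_history_model(em, spec = "differential_interaction",
                                   backend = backend)
    ct$estimate[ct$term == "differential_evidence:Condition"]
  })
  out <- list(null_estimates = est,
              range95 = unname(quantile(est, c(0.025, 0.975))))
  if (!is.null(observed)) {
    out$observed <- observed
    out$p_value <- (1 + sum(abs(est) >= abs(observed))) / (n_groups + 1)
  }
  structure(out, class = "heist_permnull")
}

#' Outcome-valence consistency scores
#'
#' Classifies each eligible trial by whether the previous trial's terminal
#' state should be revisited (*repeat*: previous heist on a current gain
#' trial, or previous neutral on a current loss trial) or avoided (*switch*).
#' A choice is consistent when it repeats the previous door on repeat trials
#' or switches door on switch trials. Trials are split by the valence of the
#' previous outcome (positive: +1 on a gain trial or 0 on a loss trial;
#' negative: -1 on a loss trial or 0 on a gain trial) and the percentage of
#' consistent choices is returned per valence. The previous trial is the
#' immediately preceding trial within the same block, regardless of context;
#' first trials of a block and pairs involving missed trials are excluded.
#'
#' @param trials A trial table with filled choices/states/outcomes.
#' @param scope `"all"` or `"dependent_only"` (restrict current trials to
#'   dependent blocks).
#' @param free_only Score free-choice trials only (the in-scanner design;
#'   the pilot design is all-free so this is equivalent there).
#' @return A tibble (class `heist_consistency`) with one row per subject:
#'   `consistency_positive`, `consistency_negative` (percentages),
#'   `valence_effect` (their difference in percentage points) and the four
#'   category counts.
#' @export
consistency_scores <- function(trials, scope = c("all", "dependent_only"),
                               free_only = TRUE) {
  scope <- match.arg(scope)
  out <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(~ consistency_one_subject(.x, scope, free_only)) |>
    dplyr::ungroup()
  class(out) <- c("heist_consistency", class(out))
  out
}

consistency_one_subject <- function(df, scope, free_only) {
  if (is.unsorted(df$trial)) abort("trials must be time-ordered within subject")
  n <- nrow(df)
  block_id <- paste(df$session, df$block)
  prev <- c(NA_integer_, seq_len(n - 1L))
  valid_choice <- !is.na(df$choice) & df$choice != "missed"
  ok <- seq_len(n) > 1L &
    block_id == c("", block_id[-n]) &
    valid_choice & c(FALSE, valid_choice[-n])
  if (free_only) ok <- ok & df$trial_type == "free"
  if (scope == "dependent_only") ok <- ok & df$condition == "dependent"
  idx <- which(ok)
  p <- prev[idx]
  prev_state <- df$state[p]
  prev_choice <- df$choice[p]
  prev_valence <- df$valence[p]
  cur_valence <- df$valence[idx]
  choice <- df$choice[idx]

  repeat_trial <- (prev_state == "heist" & cur_valence == "gain") |
    (prev_state == "neutral" & cur_valence == "loss")
  consistent <- ifelse(repeat_trial, choice == prev_choice,
                       choice != prev_choice)
  positive_prev <- (prev_state == "heist" & prev_valence == "gain") |
    (prev_state == "neutral" & prev_valence == "loss")

  pct <- function(v) if (length(v)) 100 * mean(v) else NA_real_
  tibble::tibble(
    consistency_positive = pct(consistent[positive_prev]),
    consistency_negative = pct(consistent[!positive_prev]),
    valence_effect = consistency_positive - consistency_negative,
    n_repeat_positive = sum(repeat_trial & positive_prev),
    n_repeat_negative = sum(repeat_trial & !positive_prev),
    n_switch_positive = sum(!repeat_trial & positive_prev),
    n_switch_negative = sum(!repeat_trial & !positive_prev)
  )
}
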