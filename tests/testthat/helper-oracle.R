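# Independent step-by-step reference for the dual-learner model, written as
# a direct transcription of the update equations (kept separate from the
# package's compiled implementation so the two can be compared).
oracle_run <- function(trials, alpha, beta, w, flexible = TRUE) {
  p_spec <- c(`1` = 0.5, `2` = 0.5, `3` = 0.5, `4` = 0.5)
  p_ind <- c(dependent = 0.5, independent = 0.5)
  n <- nrow(trials)
  p_hat <- rep(NA_real_, n)
  p_dark <- rep(NA_real_, n)
  delta <- rep(NA_real_, n)
  ll <- rep(0, n)
  for (t in seq_len(n)) {
    cond <- trials$condition[t]
    ctx <- as.character(trials$context[t])
    ch <- trials$choice[t]
    if (is.na(ch) || ch == "missed") next
    w_eff <- if (flexible && cond == "independent") 1 - w else w
    ph <- w_eff * p_ind[[cond]] + (1 - w_eff) * p_spec[[ctx]]
    r <- if (trials$valence[t] == "gain") 1 else -1
    q_dark <- r * ph
    q_light <- r * (1 - ph)
    pd <- 1 / (1 + exp(beta * (q_light - q_dark)))
    p_hat[t] <- ph
    p_dark[t] <- pd
    if (trials$trial_type[t] == "free") {
      ll[t] <- log(if (ch == "dark") pd else 1 - pd)
    }
    st <- trials$state[t]
    x <- if ((ch == "dark" && st == "heist") ||
             (ch == "light" && st == "neutral")) 1 else 0
    d <- x - ph
    delta[t] <- d
    p_ind[[cond]] <- min(1, max(0, p_ind[[cond]] + w_eff * alpha * d))
    p_spec[[ctx]] <- min(1, max(0, p_spec[[ctx]] + (1 - w_eff) * alpha * d))
  }
  list(p_hat = p_hat, choice_prob_dark = p_dark, delta = delta,
       loglik_contribution = ll, loglik = sum(ll))
}
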