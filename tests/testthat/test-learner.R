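test_that("combined estimate mixes the two learners with the right weight", {
  b <- belief_state()
  b$p_independent["dependent"] <- 0.7
  b$p_specific["1"] <- 0.5
  p_full <- model_params(0.5, 1, 1)
  expect_equal(combined_estimate(b, p_full, "dependent", 1, "fixed"), 0.7)

  p8 <- model_params(0.5, 1, 0.8)
  expect_equal(combined_estimate(b, p8, "dependent", 1, "fixed"), 0.66)

  b$p_independent["independent"] <- 0.7
  b$p_specific["3"] <- 0.5
  expect_equal(combined_estimate(b, p8, "independent", 3, "flexible"),
               0.2 * 0.7 + 0.8 * 0.5)
  expect_equal(combined_estimate(b, p8, "independent", 3, "fixed"), 0.66)

  expect_error(combined_estimate(b, p8, "dependent", 3, "fixed"),
               "does not belong")
})

test_that("action values and softmax follow the valence-signed rule", {
  flat <- action_values(0.8, "gain", beta = 0)
  expect_equal(flat$choice_prob_dark, 0.5)
  sym <- action_values(0.5, "loss", beta = 3)
  expect_equal(sym$choice_prob_dark, 0.5)
  expect_equal(sym$q_dark, sym$q_light)

  av <- action_values(0.61, "gain", beta = 1)
  expect_equal(av$q_dark, 0.61)
  expect_equal(av$q_light, 0.39)
  expect_equal(av$choice_prob_dark, 1 / (1 + exp(-0.22)))

  # loss trials invert preferences
  av_loss <- action_values(0.61, "loss", beta = 1)
  expect_true(av_loss$choice_prob_dark < 0.5)

  # complement and monotonicity
  p <- action_values(seq(0.1, 0.9, 0.1), "gain", beta = 2)$choice_prob_dark
  expect_true(all(diff(p) > 0))
})

test_that("state prediction errors code surprise about the reached state", {
  expect_equal(state_prediction_error("dark", "heist", 0.5), 0.5)
  expect_equal(state_prediction_error("light", "neutral", 1.0), 0)
  expect_equal(state_prediction_error("dark", "neutral", 0.8), -0.8)
  expect_equal(state_prediction_error("light", "heist", 0.3), -0.3)
  expect_error(state_prediction_error("missed", "heist", 0.5), "missed")
})

test_that("belief updates split alpha*delta by the effective weight and clamp", {
  b <- belief_state()
  p <- model_params(0.5, 1, 0.8)

  b0 <- update_beliefs(b, 0.5, model_params(0, 1, 0.8), "dependent", 1, "fixed")
  expect_equal(b0, b)

  b1 <- update_beliefs(b, 0.5, p, "dependent", 1, "fixed")
  expect_equal(unname(b1$p_independent["dependent"]), 0.7)
  expect_equal(unname(b1$p_specific["1"]), 0.55)
  expect_equal(unname(b1$p_specific["2"]), 0.5) # untouched
  expect_equal(unname(b1$p_independent["independent"]), 0.5)

  b$p_specific["1"] <- 0.99
  b2 <- update_beliefs(b, 0.5, model_params(0.5, 1, 0.6), "dependent", 1, "fixed")
  expect_equal(unname(b2$p_specific["1"]), 1.0) # clamped

  # pre-clamp increments sum to alpha * |delta|
  d <- 0.3; pm <- model_params(0.4, 1, 0.65)
  b3 <- update_beliefs(belief_state(), d, pm, "dependent", 2, "fixed")
  inc <- abs(b3$p_independent["dependent"] - 0.5) + abs(b3$p_specific["2"] - 0.5)
  expect_equal(unname(inc), 0.4 * 0.3)
})

test_that("the flexible variant reverses the weight in the independent condition", {
  b <- belief_state()
  p <- model_params(0.5, 1, 0.8)
  b4 <- update_beliefs(b, 0.4, p, "independent", 4, "flexible")
  # effective weight on the independent learner is 1 - w = 0.2
  expect_equal(unname(b4$p_independent["independent"]), 0.5 + 0.2 * 0.5 * 0.4)
  expect_equal(unname(b4$p_specific["4"]), 0.5 + 0.8 * 0.5 * 0.4)
})

test_that("run_model reproduces the hand-computed 3-trial sequence", {
  traj <- run_model(hand_three_trials(), model_params(0.5, 1, 0.8), "flexible")
  # by hand: gain 0.34 per heist observation
  # t1 p=0.5; update p_ind->0.7, p_spec->0.55
  # t2 p=0.8*0.7+0.2*0.55=0.67; update p_ind->0.832, p_spec->0.583
  # t3 p=0.8*0.832+0.2*0.583=0.7822
  expect_equal(traj$p_hat, c(0.5, 0.67, 0.7822), tolerance = 1e-12)
  oracle <- oracle_run(hand_three_trials(), 0.5, 1, 0.8, flexible = TRUE)
  expect_equal(traj$p_hat, oracle$p_hat, tolerance = 1e-12)
})

test_that("run_model matches the independent oracle on random fixtures", {
  set.seed(10)
  for (k in 1:20) {
    tt <- random_filled_table(n_sessions = 2L, trials_per_block = 26L,
                              forced = 18L, free = 8L)
    alpha <- runif(1); beta <- runif(1, 0, 4); w <- runif(1)
    flex <- k %% 2 == 0
    variant <- if (flex) "flexible" else "fixed"
    traj <- run_model(tt, model_params(alpha, beta, w), variant)
    orc <- oracle_run(tt, alpha, beta, w, flexible = flex)
    expect_equal(traj$p_hat, orc$p_hat, tolerance = 1e-12)
    expect_equal(traj$delta, orc$delta, tolerance = 1e-12)
    expect_equal(traj$choice_prob_dark, orc$choice_prob_dark, tolerance = 1e-12)
    expect_equal(attr(traj, "loglik"), orc$loglik, tolerance = 1e-10)
    expect_equal(model_loglik(tt, model_params(alpha, beta, w), variant),
                 orc$loglik, tolerance = 1e-10)
  }
})

test_that("likelihood sums only over free non-missed trials", {
  tt <- hand_three_trials() # all forced
  traj <- run_model(tt, model_params(0.5, 1, 0.8), "flexible")
  expect_equal(attr(traj, "loglik"), 0)
  expect_true(all(traj$loglik_contribution == 0))

  # a missed trial contributes nothing and does not update beliefs
  tt2 <- tt
  tt2$trial_type <- "free"
  tt2$choice[2] <- "missed"
  tt2$state[2] <- NA_character_
  traj2 <- run_model(tt2, model_params(0.5, 1, 0.8), "flexible")
  expect_true(is.na(traj2$p_hat[2]))
  expect_equal(traj2$loglik_contribution[2], 0)
  # beliefs after trial 1 carry straight to trial 3
  expect_equal(traj2$p_hat[3], 0.67, tolerance = 1e-12)
})

test_that("a near-deterministic agent picks the higher-valued door", {
  set.seed(11)
  tt <- random_filled_table()
  tt$choice <- NA_character_; tt$state <- NA_character_; tt$outcome <- NA_integer_
  traj <- run_model(tt, model_params(0.5, 50, 0.8), "fixed", mode = "simulate")
  free <- which(tt$trial_type == "free" & abs(traj$p_hat - 0.5) > 0.05)
  gain <- tt$valence[free] == "gain"
  want_dark <- ifelse(gain, traj$p_hat[free] > 0.5, traj$p_hat[free] < 0.5)
  expect_true(all((traj$choice[free] == "dark") == want_dark))
})

test_that("beliefs stay in [0, 1] under adversarial input streams (fuzz)", {
  set.seed(12)
  for (k in 1:10) {
    tt <- random_filled_table()
    # force long runs of identical transitions to push beliefs to the bounds
    tt$state <- ifelse(tt$choice == "dark", "heist", "neutral")
    tt$outcome <- ifelse(tt$state == "neutral", 0L,
                         ifelse(tt$valence == "gain", 1L, -1L))
    traj <- run_model(tt, model_params(1, 2, runif(1)), "flexible")
    expect_true(all(traj$p_hat >= 0 & traj$p_hat <= 1))
  }
})

test_that("parameter constructors validate bounds", {
  expect_error(model_params(-0.1, 1, 0.5), "alpha")
  expect_error(model_params(0.5, -1, 0.5), "beta")
  expect_error(model_params(0.5, 1, 1.2), "w")
})
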