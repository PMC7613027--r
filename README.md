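# heistrl

Simulation and analysis of **context-dependent sharing of state-transition
models** in a two-stage planning task (the "heist" task), for researchers in
computational cognitive neuroscience who want to simulate the task, fit and
compare the dual-learner reinforcement-learning model hierarchically, and
run the accompanying behavioural and multivariate (RSA / encoding-model)
analyses on synthetic multivoxel data.

## The problem and the model

On each trial a door (dark/light) appears in one of four visual contexts
("gems"). The dark door leads to a *heist* state with probability *p* and to
a *neutral* state otherwise (the light door has the complementary
probabilities); a cue signals whether the heist state currently pays +1 or
−1, the neutral state always pays 0. *p* alternates between 0.2 and 0.8 with
hazard 0.1 per trial. In *dependent* blocks the two contexts share a single
schedule of *p*; in *independent* blocks their schedules are unrelated. An
efficient agent should therefore share one transition model across contexts
in dependent blocks and keep context-specific models in independent blocks.

The package's core model tracks *p* with two learners — context-independent
(*p*<sub>ind</sub>) and context-specific (*p*<sub>spec</sub>) — mixed at
choice by a weight *w*:

> p̂ = w·p<sub>ind</sub> + (1 − w)·p<sub>spec</sub>,
> Q<sub>dark</sub> = r·p̂, Q<sub>light</sub> = r·(1 − p̂),
> P(dark) = 1/(1 + exp(β(Q<sub>light</sub> − Q<sub>dark</sub>))),

with r = ±1 for gain/loss cues. After each transition a state prediction
error δ = x − p̂ updates both learners (p<sub>ind</sub> += w·α·δ,
p<sub>spec</sub> += (1 − w)·α·δ, clamped to [0, 1]). The *fixed* variant
keeps *w* constant; the *flexible* variant reverses it (1 − w) in the
independent condition. Subjects are fitted jointly by hierarchical
Expectation-Maximization with Gaussian group priors on transformed
parameters, compared by subject-level leave-one-out cross-validated Laplace
marginal likelihoods.

Around the model, the package implements the task's behavioural statistics
(5-lag same/other-context transition-evidence regressions, the
differential-evidence × condition interaction with an agent-based
permutation null, outcome-valence consistency scores) and two multivariate
analyses run on a synthetic trial-by-voxel generator with shared or
context-specific codes: cross-context RSA (Fisher-z on/off-diagonal
contrasts, cross-run cross-validation, temporal-proximity control) and a
cross-validated linear encoding model over binned transition probabilities
scored by cross-entropy.

## Worked example

```r
library(heistrl)
set.seed(7)

# one synthetic subject playing the scanner design (320 trials)
sub <- simulate_subject(model_params(alpha = 0.56, beta = 1.6, w = 0.85),
                        "flexible")
dplyr::select(sub, trial, condition, context, valence, choice, state,
              p_hat, delta)[1:5, ]
#>   trial condition   context valence choice state   p_hat  delta
#> 1     1 independent       4 gain    light  heist   0.5   -0.5
#> 2     2 independent       4 gain    light  neutral 0.291  0.709
#> 3     3 independent       4 loss    dark   heist   0.587  0.413
#> 4     4 independent       3 gain    light  neutral 0.508  0.492
#> 5     5 independent       3 loss    dark   neutral 0.713 -0.713
attr(sub, "loglik")
#> -48.14
```

`p_hat` is the agent's current mixed estimate that the dark door leads to
the heist state, and `delta` the state prediction error that drives the next
update; the log likelihood sums over the 80 free-choice trials.

Fitting a cohort and reading the group level:

```r
cohort <- lapply(1:8, function(i) {
  p <- sample_params_pool(1, "flexible")
  simulate_subject(model_params(p$alpha, p$beta, p$w), "flexible", subject = i)
})
fit <- em_fit(cohort, "flexible")
glance(fit)   # group-level natural-scale means, evidence, convergence
tidy(fit)     # per-subject MAP parameters and Laplace evidence
```

The behavioural signature of model sharing — past transitions from the
*other* context predict choice in dependent but not independent blocks —
comes out of the lagged-evidence regression:

```r
em <- build_history_regressors(dplyr::bind_rows(cohort))
fit_choice_history_model(em[em$condition == "dependent", ], "ten_lag")
#> # A tibble: 11 × 6  (term, estimate, std_error, conf_low, conf_high, p_value)
#> 1 (Intercept)    -0.114     0.124   -0.357      0.128  0.355
#> 2 oneBackSame     0.895     0.395    0.121      1.67   0.0234
#> ...
```

`simulate_neural_cohort()`, `rsa_condition_contrast()`,
`condition_interaction()`, `generalization_contrast()` and
`encoding_condition_test()` provide the multivariate side; see the methods
vignette (`vignettes/heistrl-methods.Rmd`) for the models, parameter
defaults, and numerical choices.

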