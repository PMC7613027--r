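---
title: "Models and methods behind heistrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heistrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heistrl)
```

# The task and what the package computes

The heist task is a two-stage planning task built to ask one question: when
do people *share* a model of the world's transition structure across sensory
contexts, and when do they keep context-specific models? On each trial a
door (dark or light) is presented in one of four visual contexts ("gems").
The dark door leads to a high-stakes "heist" state with probability $p$ and
to a neutral state otherwise; the light door has the complementary
probabilities. A cue shown before choice signals whether reaching the heist
state pays +1 (gain) or −1 (loss); the neutral state always pays 0, so the
optimal policy is to track $p$ and to approach the heist state on gain
trials and avoid it on loss trials. $p$ alternates between 0.2 and 0.8 with
a per-trial hazard of 0.1. Blocks pair two contexts: in *dependent* blocks
both contexts share one schedule of $p$; in *independent* blocks the two
schedules are unrelated. In the scanner design, 24 of each 32-trial block's
trials are forced (the presented door must be taken; transitions still teach)
and 8 are free choices; 5 sessions of two blocks give 320 trials.

`heistrl` implements the full analysis chain for this task: the task
simulator, the dual-learner reinforcement-learning model and its
hierarchical fit, the behavioural trial-history statistics, and two
multivariate analyses (representational similarity analysis and a linear
encoding model) applied to synthetic multivoxel patterns.

# The dual-learner model

The agent tracks $p$ (the dark-door-to-heist probability) with two learners:
a context-independent estimate $p_{\mathrm{ind}}$ (one per condition's
context pair) and context-specific estimates $p_{\mathrm{spec}}^{(c)}$ (one
per context), all initialised at 0.5 and never reset between blocks. At
choice they are mixed,

$$\hat p = w_\mathrm{eff}\, p_{\mathrm{ind}} + (1 - w_\mathrm{eff})\,
  p_{\mathrm{spec}}^{(c)},$$

action values are $Q_\mathrm{dark} = r \hat p$ and
$Q_\mathrm{light} = r (1 - \hat p)$ with $r = \pm 1$ for gain/loss cues, and
the dark door is chosen with probability
$1 / (1 + e^{\beta (Q_\mathrm{light} - Q_\mathrm{dark})})$. After the
transition, a state prediction error $\delta = x - \hat p$ (with $x = 1$ for
dark→heist or light→neutral) updates both learners:
$p_{\mathrm{ind}} \mathrel{+}= w_\mathrm{eff}\,\alpha\,\delta$ and
$p_{\mathrm{spec}}^{(c)} \mathrel{+}= (1 - w_\mathrm{eff})\,\alpha\,\delta$,
each clamped to $[0, 1]$ after its own update. Updates happen on every
non-missed trial (forced included); only free-choice trials enter the
likelihood. The *fixed* variant uses $w_\mathrm{eff} = w$ everywhere; the
*flexible* variant reverses it to $1 - w$ in the independent condition,
giving it the capacity to share a model where sharing helps and to segregate
where it does not.

Three parameters per subject: learning rate $\alpha \in [0,1]$, softmax
inverse temperature $\beta \ge 0$, and the mixing weight $w \in [0,1]$.
The sequential likelihood loop is compiled (Rcpp) because the hierarchical
fit, cross-validation, and permutation analyses together require on the
order of $10^5$ sequential 320-trial evaluations.

Two scoping choices the verbal model description leaves open are made
explicit here: $p_{\mathrm{ind}}$ is kept per condition pair and carries
across that condition's blocks (beliefs are never reset), and clamping is
applied to each learner's update separately. Missed trials consume no
estimate and trigger no update.

# Hierarchical fitting

Subjects are fitted jointly with a Gaussian group prior over transformed
parameters (logit for $\alpha$ and $w$, log for $\beta$) by
Expectation-Maximization. The E-step computes each subject's MAP in
transformed space (BFGS; the first iteration uses jittered restarts, later
iterations warm-start from the previous MAP and from the first iteration's
wide-prior MAP, which protects against the collapse that occurs when a
tightening prior traps estimates in the central basin of a multimodal
likelihood). The Laplace approximation gives each subject's log marginal
likelihood from the negative log posterior at the MAP and a central
finite-difference Hessian. The M-step re-estimates the group mean and
(diagonal) variance from the MAPs plus their posterior variances, floored at
$10^{-6}$.

Numerical choices that matter:

* **Hessian step.** The finite-difference step is $10^{-2}$ in transformed
  space, about $\varepsilon^{1/4}$. Much smaller steps produce second
  differences of order $H h^2 \approx 10^{-8}$, at the objective's noise
  floor, which yields spurious curvature, underestimated posterior
  variances, and a collapsing group variance.
* **Eigenvalue floor.** Hessian eigenvalues are floored at the prior
  precision (a Gaussian posterior cannot be wider than its prior), with
  $10^{-6}$ as an absolute backstop. Flooring at $10^{-6}$ alone lets flat
  likelihood directions contribute posterior variances of $10^{6}$ and
  explode the group variance.
* **Convergence.** The summed Laplace evidence carries finite-difference
  noise of roughly 0.02 at $n = 29$, so an evidence tolerance of $10^{-4}$
  alone never triggers; the fit also stops when no group-prior element moves
  by more than `prior_tol` (default $10^{-3}$) between M-steps.

Model comparison uses subject-level leave-one-out cross-validation: the
hierarchy is refitted without each subject and the held-out subject is
scored by the negative Laplace log marginal under the left-out group prior
(lower is better), compared between variants with a two-sided paired t-test.
Absolute scores depend on Laplace constants and transform conventions;
between-model differences are the meaningful quantity.

# Synthetic cohorts

Synthetic subjects are drawn from the hierarchy's own group law — Gaussians
in transformed space — centred on the reported group-level fits (flexible:
$\alpha = 0.56$, $\beta = 1.59$, $w_\mathrm{dep} = 0.85$; fixed:
$\alpha = 0.65$, $\beta = 1.80$, $w = 0.61$). The reported 95% confidence
intervals imply between-subject natural-scale SDs of roughly 0.4–0.5 for the
bounded parameters, which no unimodal distribution on $[0, 1]$ can attain at
those means; the generator therefore uses transformed-space SD 2.0 for
$\alpha$ and $w$ (natural-scale SD about 0.3, the closest feasible choice)
and the log-scale SD implied by the $\beta$ interval. Draws are clamped to
$[0.02, 0.98]$ ($\alpha$, $w$) and $[0.05, 10]$ ($\beta$) so transforms stay
finite.

Recovery under these conditions is information-limited: with $\beta \approx
1.6$ and only 80 free-choice trials per subject the likelihood profile over
$w$ is shallow for many subjects, and even an oracle that knows each
subject's true $\alpha$ and $\beta$ ranks subjects' $w$ at Spearman
$\rho \approx 0.3$–$0.7$ depending on the cohort draw. Group *means* are
recovered much more stably than subject *ranks*; both are exercised in the
test suite.

# Behavioural statistics

**Lagged evidence regressions.** For each free, non-missed trial, the
transition observed $n$ trials back ($n \le 5$, within block) is coded +1
when it supports choosing the dark door on a current gain trial (dark→heist
or light→neutral) and −1 otherwise, with the coding reversed on current loss
trials, and routed to a `Same` or `Other` column by whether the source trial
shared the current trial's context. The ten lag terms are fitted per
condition as a logistic regression on the recoded choice. *Differential
evidence* is the mean `Same` minus mean `Other` evidence over the five lags;
a third model fits `differential_evidence * Condition` (+1 dependent, −1
independent). The mixed-effects specification (all regressors random across
subjects, diagonal covariance via `lme4`) is available; the default backend
for simulated cohorts is a fixed-effects logistic fit with cluster-robust
(by subject) standard errors, because the fully crossed 11-term
random-effects model is frequently singular at $n = 29$ and orders of
magnitude slower across hundreds of simulated groups, while the
fixed-effect estimates — the quantity averaged over simulations — agree.

**Agent-based permutation null.** To ask whether a
differential-evidence-by-condition interaction could arise from feedback
similarity alone, groups of 29 fixed-model agents (no reversal, $w \sim
U(0,1)$, $\alpha, \beta$ resampled from the fixed pool) are simulated and
the interaction refitted per group; the observed estimate is scored against
this null's 95% range and by a two-sided empirical $p$ with the $+1$
continuity correction.

**Consistency scores.** Each eligible trial is classified *repeat* (previous
heist + current gain, or previous neutral + current loss) or *switch*
(otherwise); a choice is consistent when it repeats or switches the previous
door accordingly. Trials split by the previous outcome's valence (positive:
+1, or 0 on a loss trial; negative: −1, or 0 on a gain trial); the
percentage consistent per valence and their difference (the *valence
effect*) are returned per subject. The previous trial is the immediately
preceding trial in the same block regardless of context; block-initial and
missed-adjacent trials are excluded.

A caution discovered in simulation and encoded in the tests: symmetric
updaters do *not* have an exactly null valence effect in this task.
Conditioning on the previous outcome's valence selects belief-disconfirming
transitions into the negative class, and a single symmetric update often
cannot carry the belief past 0.5, so the measured effect grows with choice
determinism (about +1 point at $\beta = 0.5$, +7 at 1.6, +12 at 3). The
clean null holds only in the weakly deterministic regime, and the package's
tests therefore check that null at low $\beta$ and that positive-only
updaters exceed matched symmetric agents — a comparative, not absolute,
signature.

# Synthetic multivoxel patterns

The voxel generator stands in for single-trial BOLD estimates. Each
(context, bin) cell has a voxel-length prototype drawn i.i.d. standard
normal; "shared" coding copies prototypes across a condition's two contexts,
"separate" coding draws them independently. A trial's pattern is its cell
prototype plus a per-run voxel offset (SD 0.5, drawn once per run so
cross-run cross-validation is non-trivial) plus i.i.d. Gaussian noise. In
door mode the bin is the fixed-quartile bin of
$p(\text{heist} \mid \text{door presented})$ — $\hat p$ or $1 - \hat p$ by
the presented door — and in outcome mode the four choice-by-state
combinations. Defaults: 200 voxels (a small ROI), sessions as runs, and
`noise_sd = 8`, calibrated once so that the dependent-condition on–off
diagonal Fisher-z difference per subject is about 0.15, the scale of the
reported effect (0.18, CI [.11, .26]).

What the generator does *not* emulate: spatial autocorrelation between
voxels, haemodynamics, scanner drift, within-condition heterogeneity of
coding fidelity across subjects, or any relation between behavioural and
neural noise. Passing tests on these patterns show that the statistics
recover planted structure at realistic effect sizes, not that real BOLD data
would behave this way.

# RSA

Per subject and condition, trials are binned (subject-specific quartiles of
the presented-door heist probability by default; the fixed edges
0–.25/.26–.50/.51–.75/.76–1.00 as a robustness variant; choice-by-state
combinations at outcome time), bin-mean patterns are computed per context
collapsing across runs, and every bin of context A is correlated with every
bin of context B. The resulting 4×4 matrix is used as-is (it is not
symmetric); correlations are clipped at $|r| \le 1 - 10^{-6}$, Fisher
transformed, and summarised as the mean of the 4 diagonal cells minus the
mean of the 12 off-diagonal cells. A positive difference means identical
transition probabilities are encoded more similarly across contexts than
different ones. The condition-by-diagonal interaction is a paired t-test on
per-subject differences; cross-run variants correlate bin means only across
run pairs $i \ne j$, between or within contexts; and the temporal-proximity
control correlates, across subjects, the diagonal-versus-off-diagonal
difference in mean inter-trial temporal distance with the RSA difference.
Searchlight mapping is out of scope: the per-ROI statistic implemented here
is the unit a searchlight would map over spheres.

# Encoding model

Model-derived probabilities are converted to log-odds, clipped to
$[-2, 2]$, and binned into $n$ equal-width bins ($n = 1,\dots,10$), as a
one-hot indicator or a unit-normalised Gaussian tuning curve (width = one
bin width by default). Weights are fitted by least squares from the design
to each voxel (tiny ridge, $10^{-6}$, for rank-deficient designs). Decoding
inverts the weights by least squares on held-out patterns and maps bin
scores to probabilities with a softmax; the loss is the mean cross-entropy
of the true bins, with $\ln n$ as chance. The softmax gain (temperature) is
the readout scale of the equivalent cross-validated multinomial logistic
regression and is cross-fitted within the training cell (interleaved
split-halves; no test labels), which keeps chance-level data at $\ln n$
within a couple of percent where raw unscaled scores overshoot by 4–15%.
Generalization trains on each (context, run) cell and decodes the paired
context's trials in the other runs; dependent-minus-independent loss
differences are paired-tested across subjects per bin count. Under a 4-level
planted code this contrast is reliable for $n \ge 4$ and unreliable at
coarser binning once the decoder is calibrated, echoing the reported
bin-count dependence.

# Problem sizes in the test suite

The acceptance-style tests run the full chain at the study's scale where
that is cheap (29 subjects for the EM fit, the RSA cohorts, the encoding
cohort, and the permutation observed group) and at reduced sizes for the
heavily repeated fits, chosen as the package's own test design: 20 + 20
model-recovery cohorts of 7 subjects with capped EM iterations, 30
simulated groups per variant for the evidence-pattern check, and 100
permutation groups (the reference procedure uses 500). The acceptance
script reports the same quantities at comparable sizes.

# Known limitations

* The model is an analytic device, not a process account; no change-point
  or structure-inference learners are provided.
* LOOcv scores are comparable between models, not across implementations
  (Laplace constants and transform conventions shift absolute values).
* Subject-level $w$ ranks are information-limited at the reference
  $\beta$; see the recovery discussion above.
* The voxel generator's independence assumptions make multivariate effects
  cleaner than real BOLD; temporal-proximity structure, for instance, only
  appears if planted.
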