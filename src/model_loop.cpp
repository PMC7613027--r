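#include <Rcpp.h>
using namespace Rcpp;

// Integer codings shared with the R wrappers (see R/learner.R):
//   condition: 1 dependent, 2 independent
//   context:   1..4 (1,2 dependent; 3,4 independent by default, but any
//              context id consistent with its condition works)
//   valence:   1 gain, 2 loss
//   trial_type:1 forced, 2 free
//   choice:    1 dark, 2 light, 0 missed
//   state:     1 heist, 2 neutral, 0 missing
//   door:      1 dark, 2 light

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Sequential dual-learner pass over one subject's trials.
//
// Beliefs: p_spec (one per context id) and p_ind (one per condition) all
// start at 0.5 and are never reset within the pass; callers pass a subject's
// full, time-ordered trial table so beliefs carry across blocks.
//
// In likelihood mode, `choice` and `state` are observed; the returned
// `loglik` sums log choice probabilities over free, non-missed trials only
// (updates happen on every non-missed trial, forced or free).
//
// In simulate mode, the forced-trial choice is the presented door and the
// free-trial choice is sampled from the softmax; the transitioned state is
// sampled from p_true, and the outcome follows from state and valence.
// [[Rcpp::export]]
List model_pass_cpp(IntegerVector condition, IntegerVector context,
                    IntegerVector valence, IntegerVector trial_type,
                    IntegerVector choice, IntegerVector state,
                    IntegerVector door, NumericVector p_true,
                    double alpha, double beta, double w,
                    bool flexible, bool simulate, bool trajectory) {
  const int n = condition.size();
  std::map<int, double> p_spec;
  double p_ind[3] = {0.5, 0.5, 0.5}; // index 1,2 used

  NumericVector p_hat_v, q_dark_v, q_light_v, pdark_v, delta_v, ll_v;
  IntegerVector sim_choice, sim_state, sim_outcome;
  if (trajectory) {
    p_hat_v = NumericVector(n, NA_REAL);
    q_dark_v = NumericVector(n, NA_REAL);
    q_light_v = NumericVector(n, NA_REAL);
    pdark_v = NumericVector(n, NA_REAL);
    delta_v = NumericVector(n, NA_REAL);
    ll_v = NumericVector(n, 0.0);
  }
  if (simulate) {
    sim_choice = IntegerVector(n);
    sim_state = IntegerVector(n);
    sim_outcome = IntegerVector(n);
  }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) {
    const int cond = condition[t];
    const int ctx = context[t];
    if (p_spec.find(ctx) == p_spec.end()) p_spec[ctx] = 0.5;

    const double w_eff = (flexible && cond == 2) ? (1.0 - w) : w;
    const double p_hat = w_eff * p_ind[cond] + (1.0 - w_eff) * p_spec[ctx];

    const double r = (valence[t] == 1) ? 1.0 : -1.0;
    const double q_dark = r * p_hat;
    const double q_light = r * (1.0 - p_hat);
    const double p_dark = 1.0 / (1.0 + std::exp(beta * (q_light - q_dark)));

    int ch, st;
    if (simulate) {
      if (trial_type[t] == 1) {
        ch = door[t]; // forced: presented door (a fair coin in the generator)
      } else {
        ch = (R::runif(0.0, 1.0) < p_dark) ? 1 : 2;
      }
      const double u = R::runif(0.0, 1.0);
      const double p_heist = (ch == 1) ? p_true[t] : 1.0 - p_true[t];
      st = (u < p_heist) ? 1 : 2;
      sim_choice[t] = ch;
      sim_state[t] = st;
      sim_outcome[t] = (st == 2) ? 0 : ((valence[t] == 1) ? 1 : -1);
    } else {
      ch = choice[t];
      st = state[t];
    }

    if (ch == 0) continue; // missed: no p_hat consumed, no update, no likelihood

    if (trajectory) {
      p_hat_v[t] = p_hat;
      q_dark_v[t] = q_dark;
      q_light_v[t] = q_light;
      pdark_v[t] = p_dark;
    }

    if (trial_type[t] == 2) {
      const double pc = (ch == 1) ? p_dark : (1.0 - p_dark);
      const double lc = std::log(std::max(pc, 1e-300));
      loglik += lc;
      if (trajectory) ll_v[t] = lc;
    }

    const double x = ((ch == 1 && st == 1) || (ch == 2 && st == 2)) ? 1.0 : 0.0;
    const double delta = x - p_hat;
    if (trajectory) delta_v[t] = delta;

    p_ind[cond] = clamp01(p_ind[cond] + w_eff * alpha * delta);
    p_spec[ctx] = clamp01(p_spec[ctx] + (1.0 - w_eff) * alpha * delta);
  }

  List out = List::create(_["loglik"] = loglik);
  if (trajectory) {
    out["p_hat"] = p_hat_v;
    out["q_dark"] = q_dark_v;
    out["q_light"] = q_light_v;
    out["choice_prob_dark"] = pdark_v;
    out["delta"] = delta_v;
    out["loglik_contribution"] = ll_v;
  }
  if (simulate) {
    out["choice"] = sim_choice;
    out["state"] = sim_state;
    out["outcome"] = sim_outcome;
  }
  return out;
}

// Negative log-likelihood only (hot path for the hierarchical fit).
// [[Rcpp::export]]
double model_negloglik_cpp(IntegerVector condition, IntegerVector context,
                           IntegerVector valence, IntegerVector trial_type,
                           IntegerVector choice, IntegerVector state,
                           double alpha, double beta, double w, bool flexible) {
  const int n = condition.size();
  std::map<int, double> p_spec;
  double p_ind[3] = {0.5, 0.5, 0.5};
  double loglik = 0.0;
  for (int t = 0; t < n; ++t) {
    const int cond = condition[t];
    const int ctx = context[t];
    if (p_spec.find(ctx) == p_spec.end()) p_spec[ctx] = 0.5;
    const double w_eff = (flexible && cond == 2) ? (1.0 - w) : w;
    const double p_hat = w_eff * p_ind[cond] + (1.0 - w_eff) * p_spec[ctx];
    const int ch = choice[t];
    if (ch == 0) continue;
    if (trial_type[t] == 2) {
      const double r = (valence[t] == 1) ? 1.0 : -1.0;
      const double p_dark =
          1.0 / (1.0 + std::exp(beta * (r * (1.0 - p_hat) - r * p_hat)));
      const double pc = (ch == 1) ? p_dark : (1.0 - p_dark);
      loglik += std::log(std::max(pc, 1e-300));
    }
    const double x =
        ((ch == 1 && state[t] == 1) || (ch == 2 && state[t] == 2)) ? 1.0 : 0.0;
    const double delta = x - p_hat;
    p_ind[cond] = clamp01(p_ind[cond] + w_eff * alpha * delta);
    p_spec[ctx] = clamp01(p_spec[ctx] + (1.0 - w_eff) * alpha * delta);
  }
  return -loglik;
}
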