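#include <Rcpp.h>
using namespace Rcpp;

// Stable log of the logistic function: log(1 / (1 + exp(-x)))
static inline double log_logistic(double x) {
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Core trial loop shared by likelihood evaluation and latent extraction.
//
// Encoding (one participant-session, time-ordered):
//   phase:    1 = learning, 2 = test, 3 = transfer
//   chosen:   1-based stimulus index, 0 = no choice made
//   unchosen: 1-based index of the alternative stimulus in the pair
//   reward:   1 = win, 0 = loss, -1 = no feedback
//   valid:    1 = valid response (gates likelihood/feedback-free updates)
//   dyn:      feedback-free dynamics, 0 = static, 1 = decay, 2 = cipc
//
// Learning-phase values update on every trial with feedback (own or
// observed), regardless of response validity; only valid feedback-free
// (test/transfer) choices enter the likelihood, each followed by the
// feedback-free update.
// [[Rcpp::export]]
List rl_session_core(IntegerVector phase, IntegerVector chosen,
                     IntegerVector unchosen, IntegerVector reward,
                     IntegerVector valid, double alpha_pos, double alpha_neg,
                     double beta, int dyn, double dynpar, double q0,
                     int n_stim, bool want_latents) {
  int n = phase.size();
  std::vector<double> q(n_stim, q0);
  double nll = 0.0;
  int n_ll = 0;

  NumericVector q_chosen(want_latents ? n : 0);
  NumericVector q_unchosen(want_latents ? n : 0);
  NumericVector pe(want_latents ? n : 0);
  NumericVector p_choice(want_latents ? n : 0);

  for (int i = 0; i < n; ++i) {
    int c = chosen[i], u = unchosen[i];
    double qc = NA_REAL, qu = NA_REAL;
    if (c > 0) qc = q[c - 1];
    if (u > 0) qu = q[u - 1];
    if (want_latents) {
      q_chosen[i] = qc;
      q_unchosen[i] = qu;
      pe[i] = NA_REAL;
      p_choice[i] = NA_REAL;
    }

    if (phase[i] == 1) {
      if (c > 0 && reward[i] >= 0) {
        double r = (double)reward[i];
        double delta = r - q[c - 1];
        double a = (reward[i] == 1) ? alpha_pos : alpha_neg;
        q[c - 1] += a * delta;
        if (want_latents) pe[i] = delta;
      }
    } else {
      if (c > 0 && u > 0 && valid[i] == 1) {
        double x = beta * (q[c - 1] - q[u - 1]);
        nll -= log_logistic(x);
        n_ll += 1;
        if (want_latents) p_choice[i] = 1.0 / (1.0 + std::exp(-x));
        if (dyn == 1) { // decay toward the initial value
          q[c - 1] += dynpar * (q0 - q[c - 1]);
          q[u - 1] += dynpar * (q0 - q[u - 1]);
        } else if (dyn == 2) { // choice-induced preference change
          q[c - 1] += dynpar * (1.0 - q[c - 1]);
          q[u - 1] -= dynpar * q[u - 1];
        }
      }
    }
  }

  if (want_latents) {
    return List::create(_["nll"] = nll, _["n_ll"] = n_ll,
                        _["q_chosen"] = q_chosen, _["q_unchosen"] = q_unchosen,
                        _["pe"] = pe, _["p_choice"] = p_choice);
  }
  return List::create(_["nll"] = nll, _["n_ll"] = n_ll);
}
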