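#include <Rcpp.h>
using namespace Rcpp;

// Shared trial-loop core for the eight-member RL model family.
//
// Parameter vector layout (always full length 6, constrained variants are
// expanded on the R side):
//   par[0] omega          relative-encoding weight, [0, 1]
//   par[1] alpha_con      learning rate, confirmatory outcomes
//   par[2] alpha_dis      learning rate, disconfirmatory outcomes
//   par[3] beta_learn     inverse temperature, learning phase
//   par[4] beta_transfer  inverse temperature, transfer test
//   par[5] bias           additive preference for the first-listed option
//
// Trial encoding (one row per trial, sessions contiguous):
//   pres   nt x 3 integer, 0-based option index, -1 padding
//   outc   nt x 3 double, outcomes aligned with pres (NA outside learning)
//   phase  0 = learning, 1 = transfer
//   npres  2 or 3
//   sess   integer run id; a change from the previous row resets the agent
//   choice 0-based position of the chosen option among the presented ones,
//          -1 for invalid/missing trials (skipped: no likelihood term, no
//          expectancy update, no running-range update)

namespace {

struct AgentState {
  std::vector<double> Q;
  double rmin, rmax;
  bool have_range;
  void reset(int n_options) {
    Q.assign(n_options, 0.5);
    rmin = R_PosInf;
    rmax = R_NegInf;
    have_range = false;
  }
};

// softmax choice probabilities over the presented options, overflow-safe
inline void choice_probs(const AgentState& st, const int* pres, int m,
                         double beta, double bias, double* p) {
  double u[3], umax = R_NegInf;
  for (int k = 0; k < m; ++k) {
    u[k] = beta * st.Q[pres[k]] + (k == 0 ? bias : 0.0);
    if (u[k] > umax) umax = u[k];
  }
  double z = 0.0;
  for (int k = 0; k < m; ++k) { p[k] = std::exp(u[k] - umax); z += p[k]; }
  for (int k = 0; k < m; ++k) p[k] /= z;
}

// encode this trial's outcomes (Eq. 1 with range normalization) and update
// expectancies (Eq. 2) with confirmatory/disconfirmatory learning rates
inline void encode_and_update(AgentState& st, const int* pres, const double* out,
                              int m, int chosen_pos, double omega,
                              double a_con, double a_dis) {
  double tmin = R_PosInf, tmax = R_NegInf;
  for (int k = 0; k < m; ++k) {
    if (out[k] < tmin) tmin = out[k];
    if (out[k] > tmax) tmax = out[k];
  }
  // the running range absorbs the current trial before x^ABS is computed
  if (tmin < st.rmin) st.rmin = tmin;
  if (tmax > st.rmax) st.rmax = tmax;
  st.have_range = true;
  for (int k = 0; k < m; ++k) {
    double xabs = (st.rmax > st.rmin) ? (out[k] - st.rmin) / (st.rmax - st.rmin) : 0.5;
    double xrel = (tmax > tmin) ? (out[k] - tmin) / (tmax - tmin) : 0.5;
    double v = (1.0 - omega) * xabs + omega * xrel;
    double d = v - st.Q[pres[k]];
    if (d != 0.0) {
      bool confirmatory = (k == chosen_pos) ? (d > 0.0) : (d < 0.0);
      st.Q[pres[k]] += (confirmatory ? a_con : a_dis) * d;
    }
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_loglik(NumericVector par, int n_options, IntegerMatrix pres,
                  NumericMatrix outc, IntegerVector phase, IntegerVector npres,
                  IntegerVector sess, IntegerVector choice) {
  const double omega = par[0], a_con = par[1], a_dis = par[2];
  const double b_learn = par[3], b_transfer = par[4], bias = par[5];
  const int nt = pres.nrow();
  AgentState st;
  double ll = 0.0;
  int prev_sess = NA_INTEGER;
  int prow[3];
  double orow[3], p[3];
  for (int i = 0; i < nt; ++i) {
    if (i == 0 || sess[i] != prev_sess) st.reset(n_options);
    prev_sess = sess[i];
    const int m = npres[i];
    for (int k = 0; k < m; ++k) { prow[k] = pres(i, k); orow[k] = outc(i, k); }
    const int ch = choice[i];
    if (ch < 0) continue; // invalid/missing trial: no likelihood, no update
    const bool learning = (phase[i] == 0);
    choice_probs(st, prow, m, learning ? b_learn : b_transfer, bias, p);
    if (!(p[ch] > 0.0) || !R_finite(std::log(p[ch])))
      stop("non-finite choice probability at trial %d", i + 1);
    ll += std::log(p[ch]);
    if (learning) {
      for (int k = 0; k < m; ++k)
        if (ISNAN(orow[k])) stop("missing outcome on learning trial %d", i + 1);
      encode_and_update(st, prow, orow, m, ch, omega, a_con, a_dis);
    }
  }
  return ll;
}

// [[Rcpp::export]]
IntegerVector cpp_simulate(NumericVector par, int n_options, IntegerMatrix pres,
                           NumericMatrix outc, IntegerVector phase,
                           IntegerVector npres, IntegerVector sess) {
  const double omega = par[0], a_con = par[1], a_dis = par[2];
  const double b_learn = par[3], b_transfer = par[4], bias = par[5];
  const int nt = pres.nrow();
  AgentState st;
  IntegerVector choice(nt);
  int prev_sess = NA_INTEGER;
  int prow[3];
  double orow[3], p[3];
  RNGScope rng;
  for (int i = 0; i < nt; ++i) {
    if (i == 0 || sess[i] != prev_sess) st.reset(n_options);
    prev_sess = sess[i];
    const int m = npres[i];
    for (int k = 0; k < m; ++k) { prow[k] = pres(i, k); orow[k] = outc(i, k); }
    const bool learning = (phase[i] == 0);
    choice_probs(st, prow, m, learning ? b_learn : b_transfer, bias, p);
    double r = unif_rand(), acc = 0.0;
    int ch = m - 1;
    for (int k = 0; k < m; ++k) { acc += p[k]; if (r <= acc) { ch = k; break; } }
    choice[i] = ch;
    if (learning) encode_and_update(st, prow, orow, m, ch, omega, a_con, a_dis);
  }
  return choice;
}
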