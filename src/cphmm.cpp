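#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clonal/recombined pair HMM over binary per-site difference observations.
//
// State 0 is clonal with Bernoulli(d_clonal) emissions.  States 1..K are
// recombined sub-states, one per divergence bin (Bernoulli(emit_div[k])).
// Transitions: clonal -> bin k with prob t_enter * emit_w[k]; bin k -> clonal
// with prob t_exit; no direct bin-to-bin moves.  d_clonal, t_enter and t_exit
// are re-estimated by Baum-Welch; the bin divergences and entry weights are
// held fixed (they encode the empirical distribution of local divergence).

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
List cphmm_em_cpp(IntegerVector x,
                  double d_init, double t_enter_init, double t_exit_init,
                  NumericVector emit_div, NumericVector emit_w,
                  int max_iters, double tol, double d_max) {
  const int n = x.size();
  const int K = emit_div.size();
  const int S = K + 1;
  if (n < 2) stop("profile too short for HMM decoding");

  double d = clamp(d_init, 1e-9, d_max);
  double te = clamp(t_enter_init, 1e-9, 0.5);
  double tx = clamp(t_exit_init, 1e-9, 0.5);

  // scaled forward variables, stored for the backward pass
  std::vector<double> alpha((size_t)n * S);
  std::vector<double> scale(n);
  std::vector<double> beta_next(S), beta_cur(S);
  std::vector<double> e0(S), e1(S); // emission prob of diff=0 / diff=1 per state
  std::vector<double> gamma_rec(n); // posterior recombined occupancy (last iter)

  NumericVector loglik_trace;
  double ll_prev = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iters; ++iter) {
    e0[0] = 1.0 - d;   e1[0] = d;
    for (int k = 0; k < K; ++k) { e0[k + 1] = 1.0 - emit_div[k]; e1[k + 1] = emit_div[k]; }

    const double pi_c = tx / (te + tx);

    // ---- forward ----
    double s0 = 0.0;
    {
      const double *e = (x[0] == 1) ? e1.data() : e0.data();
      alpha[0] = pi_c * e[0];
      for (int k = 0; k < K; ++k) alpha[(size_t)k + 1] = (1.0 - pi_c) * emit_w[k] * e[k + 1];
      for (int s = 0; s < S; ++s) s0 += alpha[s];
      for (int s = 0; s < S; ++s) alpha[s] /= s0;
      scale[0] = s0;
    }
    for (int t = 1; t < n; ++t) {
      const double *ap = &alpha[(size_t)(t - 1) * S];
      double *ac = &alpha[(size_t)t * S];
      const double *e = (x[t] == 1) ? e1.data() : e0.data();
      double rec_to_c = 0.0;
      for (int k = 0; k < K; ++k) rec_to_c += ap[k + 1];
      rec_to_c *= tx;
      ac[0] = (ap[0] * (1.0 - te) + rec_to_c) * e[0];
      double st = ac[0];
      const double enter = ap[0] * te;
      for (int k = 0; k < K; ++k) {
        ac[k + 1] = (enter * emit_w[k] + ap[k + 1] * (1.0 - tx)) * e[k + 1];
        st += ac[k + 1];
      }
      for (int s = 0; s < S; ++s) ac[s] /= st;
      scale[t] = st;
    }
    ll = 0.0;
    for (int t = 0; t < n; ++t) ll += std::log(scale[t]);
    loglik_trace.push_back(ll);

    // ---- backward with sufficient-statistic accumulation ----
    double occ_c = 0.0, occ_c_x = 0.0;       // clonal occupancy / diffs in clonal
    double occ_c_notlast = 0.0, occ_r_notlast = 0.0;
    double xi_enter = 0.0, xi_exit = 0.0;    // expected transition counts
    for (int s = 0; s < S; ++s) beta_next[s] = 1.0;
    {
      // gamma at final site
      const double *ac = &alpha[(size_t)(n - 1) * S];
      double gc = ac[0];
      occ_c += gc; if (x[n - 1] == 1) occ_c_x += gc;
      gamma_rec[n - 1] = 1.0 - gc;
    }
    for (int t = n - 2; t >= 0; --t) {
      const double *e = (x[t + 1] == 1) ? e1.data() : e0.data();
      const double st1 = scale[t + 1];
      double sum_w_eb = 0.0;
      for (int k = 0; k < K; ++k) sum_w_eb += emit_w[k] * e[k + 1] * beta_next[k + 1];
      const double ec_bc = e[0] * beta_next[0];
      beta_cur[0] = ((1.0 - te) * ec_bc + te * sum_w_eb) / st1;
      for (int k = 0; k < K; ++k)
        beta_cur[k + 1] = (tx * ec_bc + (1.0 - tx) * e[k + 1] * beta_next[k + 1]) / st1;

      const double *ac = &alpha[(size_t)t * S];
      // gamma(t): alpha-hat * beta-hat is already normalised under this scaling
      double gc = ac[0] * beta_cur[0];
      double gr = 0.0;
      for (int k = 0; k < K; ++k) gr += ac[k + 1] * beta_cur[k + 1];
      const double gtot = gc + gr;
      gc /= gtot; gr /= gtot;
      occ_c += gc; if (x[t] == 1) occ_c_x += gc;
      occ_c_notlast += gc; occ_r_notlast += gr;
      gamma_rec[t] = gr;

      // xi for clonal -> recombined and recombined -> clonal
      xi_enter += ac[0] * te * sum_w_eb / st1;
      double arec = 0.0;
      for (int k = 0; k < K; ++k) arec += ac[k + 1];
      xi_exit += arec * tx * ec_bc / st1;

      std::swap(beta_next, beta_cur);
    }

    const double ll_change = ll - ll_prev;
    ll_prev = ll;

    // ---- M step ----
    d = clamp(occ_c > 0 ? occ_c_x / occ_c : 1e-9, 1e-9, d_max);
    te = clamp(occ_c_notlast > 0 ? xi_enter / occ_c_notlast : 1e-9, 1e-9, 0.5);
    tx = clamp(occ_r_notlast > 0 ? xi_exit / occ_r_notlast : 1e-9, 1e-9, 0.5);

    if (iter > 0 && std::fabs(ll_change) < tol * (1.0 + std::fabs(ll))) {
      converged = true;
      break;
    }
  }

  // ---- Viterbi (log space, clonal preferred on exact ties) ----
  e0[0] = 1.0 - d; e1[0] = d;
  for (int k = 0; k < K; ++k) { e0[k + 1] = 1.0 - emit_div[k]; e1[k + 1] = emit_div[k]; }
  std::vector<double> le0(S), le1(S);
  for (int s = 0; s < S; ++s) { le0[s] = std::log(e0[s]); le1[s] = std::log(e1[s]); }
  const double l_stayc = std::log(1.0 - te), l_stayr = std::log(1.0 - tx);
  const double l_exit = std::log(tx);
  std::vector<double> l_enter(K);
  for (int k = 0; k < K; ++k) l_enter[k] = std::log(te * emit_w[k]);

  std::vector<double> dcur(S), dprev(S);
  std::vector<uint8_t> bp((size_t)n * S);
  const double pi_c = tx / (te + tx);
  {
    const double *le = (x[0] == 1) ? le1.data() : le0.data();
    dprev[0] = std::log(pi_c) + le[0];
    for (int k = 0; k < K; ++k)
      dprev[k + 1] = std::log((1.0 - pi_c) * emit_w[k]) + le[k + 1];
  }
  for (int t = 1; t < n; ++t) {
    const double *le = (x[t] == 1) ? le1.data() : le0.data();
    uint8_t *bpt = &bp[(size_t)t * S];
    // into clonal: prefer clonal predecessor on ties (strict > to replace)
    double best = dprev[0] + l_stayc; uint8_t arg = 0;
    for (int k = 0; k < K; ++k) {
      const double cand = dprev[k + 1] + l_exit;
      if (cand > best) { best = cand; arg = (uint8_t)(k + 1); }
    }
    dcur[0] = best + le[0]; bpt[0] = arg;
    for (int k = 0; k < K; ++k) {
      const double from_c = dprev[0] + l_enter[k];
      const double stay = dprev[k + 1] + l_stayr;
      if (from_c >= stay) { dcur[k + 1] = from_c + le[k + 1]; bpt[k + 1] = 0; }
      else { dcur[k + 1] = stay + le[k + 1]; bpt[k + 1] = (uint8_t)(k + 1); }
    }
    std::swap(dcur, dprev);
  }
  IntegerVector path(n);
  {
    int best_s = 0; double best = dprev[0];
    for (int s = 1; s < S; ++s) if (dprev[s] > best) { best = dprev[s]; best_s = s; }
    path[n - 1] = best_s;
    for (int t = n - 1; t > 0; --t) path[t - 1] = bp[(size_t)t * S + path[t]];
  }

  return List::create(
    _["d_clonal"] = d, _["t_enter"] = te, _["t_exit"] = tx,
    _["loglik"] = ll, _["loglik_trace"] = loglik_trace,
    _["n_iters"] = iter + 1, _["converged"] = converged,
    _["path"] = path, _["post_recomb"] = NumericVector(gamma_rec.begin(), gamma_rec.end()));
}
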