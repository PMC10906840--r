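#include <Rcpp.h>
using namespace Rcpp;

// Angular distance between two rows of M: acos(cosine similarity)/pi,
// cosine clipped into [-1, 1] before acos.
static double ang_dist_rows(const NumericMatrix& M, int i, int j) {
  const int n = M.ncol();
  double dot = 0.0, ni = 0.0, nj = 0.0;
  for (int k = 0; k < n; ++k) {
    dot += M(i, k) * M(j, k);
    ni += M(i, k) * M(i, k);
    nj += M(j, k) * M(j, k);
  }
  double c = dot / std::sqrt(ni * nj);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) / M_PI;
}

// Replay a session's state(-action) sequence under SARSA successor-matrix
// learning for a vector of discount factors simultaneously.
//
// state:    1-based indices (length n) of successive state(-action)
//           conjunctions; consecutive entries form the SARSA transitions.
// a1_state, a2_state: 1-based conjunction indices of the two actions
//           available at the room occupied on each step (used for the
//           expected-value readout of both actions; for a state-state
//           variant pass the state itself twice).
// goal_state_reward: n x S matrix? avoided -- goal is passed per step as the
//           set of state indices earning reward 1; everything else costs
//           `cost`.  goal_lo/goal_hi give the inclusive 1-based index range
//           of reward states on each step (contiguous by construction:
//           the goal room's conjunctions are adjacent).
// gamma:    vector of discount factors (replayed independently).
// lambda:   learning rate.
// n_states: number of conjunctions S (30 state-action or 15 state-state).
// want_M:   also return the final successor matrix for every gamma.
//
// Returns list with SPE, EV, EV1, EV2 (n x G matrices; SPE is NA on the
// first step) and optionally M (S x S x G array).
// [[Rcpp::export]]
List cpp_sr_replay(IntegerVector state, IntegerVector a1_state,
                   IntegerVector a2_state, IntegerVector goal_lo,
                   IntegerVector goal_hi, NumericVector gamma,
                   double lambda, double cost, int n_states,
                   bool want_M = false) {
  const int n = state.size();
  const int G = gamma.size();
  const int S = n_states;
  NumericMatrix SPE(n, G), EV(n, G), EV1(n, G), EV2(n, G);
  std::fill(SPE.begin(), SPE.end(), NA_REAL);
  NumericVector Mout;
  if (want_M) {
    Mout = NumericVector(Dimension(S, S, G));
  }
  NumericMatrix M(S, S);
  NumericVector r(S);
  for (int g = 0; g < G; ++g) {
    const double gam = gamma[g];
    std::fill(M.begin(), M.end(), 0.0);
    for (int i = 0; i < S; ++i) M(i, i) = 1.0;
    for (int t = 0; t < n; ++t) {
      const int st = state[t] - 1;
      if (t > 0) {
        const int sp = state[t - 1] - 1;
        // surprise computed from M before the update for this transition
        SPE(t, g) = ang_dist_rows(M, st, sp);
        for (int k = 0; k < S; ++k) {
          double target = gam * M(st, k) - M(sp, k);
          if (k == sp) target += 1.0;
          M(sp, k) += lambda * target;
        }
      }
      // reward vector for the current goal
      const int lo = goal_lo[t] - 1, hi = goal_hi[t] - 1;
      for (int k = 0; k < S; ++k) r[k] = (k >= lo && k <= hi) ? 1.0 : cost;
      const int s1 = a1_state[t] - 1, s2 = a2_state[t] - 1;
      double ev = 0.0, ev1 = 0.0, ev2 = 0.0;
      for (int k = 0; k < S; ++k) {
        ev += M(st, k) * r[k];
        ev1 += M(s1, k) * r[k];
        ev2 += M(s2, k) * r[k];
      }
      EV(t, g) = ev;
      EV1(t, g) = ev1;
      EV2(t, g) = ev2;
    }
    if (want_M) {
      for (int j = 0; j < S; ++j)
        for (int i = 0; i < S; ++i)
          Mout[(R_xlen_t)g * S * S + (R_xlen_t)j * S + i] = M(i, j);
    }
  }
  List out = List::create(_["SPE"] = SPE, _["EV"] = EV,
                          _["EV1"] = EV1, _["EV2"] = EV2);
  if (want_M) out["M"] = Mout;
  return out;
}

// Single SARSA update of one successor-matrix row (reference semantics are
// avoided: returns a modified copy).  Exposed for unit testing against the
// closed-form hand computation.
// [[Rcpp::export]]
NumericMatrix cpp_sr_update(NumericMatrix M, int sa_t, int sa_next,
                            double lambda, double gamma) {
  NumericMatrix out = clone(M);
  const int S = M.ncol();
  const int i = sa_t - 1, j = sa_next - 1;
  for (int k = 0; k < S; ++k) {
    double target = gamma * M(j, k) - M(i, k);
    if (k == i) target += 1.0;
    out(i, k) += lambda * target;
  }
  return out;
}

// Bernoulli log-likelihood of a response-coded logistic model evaluated at
// every column of a decision-variable grid (one column per cached discount
// value): the quadrature kernel of the choice models.
// [[Rcpp::export]]
NumericVector cpp_logistic_grid_loglik(NumericMatrix dv, NumericVector y,
                                       double alpha, double beta) {
  const int n = dv.nrow(), G = dv.ncol();
  NumericVector out(G);
  for (int g = 0; g < G; ++g) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double eta = alpha + beta * dv(i, g);
      ll += (y[i] > 0.5) ? -log1p(std::exp(-eta)) : -log1p(std::exp(eta));
    }
    out[g] = ll;
  }
  return out;
}

// Coefficient-marginalized log evidence of the lognormal regression,
// evaluated at every discount-grid node: for node g with design W_g
// (intercept + standardized regressors, Gram matrix WtW precomputed),
//   z | b, sigma ~ N(W_g b, sigma^2 I),  b ~ N(b0, diag(1/sinv))
// returns log p(z | sigma, node g) up to the gamma-independent Jacobian.
// [[Rcpp::export]]
NumericVector cpp_rt_marginal_nodes(NumericVector WtW, NumericMatrix Wtz,
                                    double zz, int n, double sigma,
                                    NumericVector b0, NumericVector sinv,
                                    double ldetS) {
  IntegerVector dims = WtW.attr("dim");
  const int p = dims[0], G = dims[2];
  const double s2 = sigma * sigma;
  NumericVector out(G);
  std::vector<double> A(p * p), L(p * p), v(p), m(p);
  double prior_quad = 0.0;
  for (int i = 0; i < p; ++i) prior_quad += b0[i] * b0[i] * sinv[i];
  for (int g = 0; g < G; ++g) {
    const double* W = &WtW[(R_xlen_t)g * p * p];
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < p; ++i)
        A[j * p + i] = W[j * p + i] / s2 + (i == j ? sinv[i] : 0.0);
    // Cholesky A = L L^T (lower)
    bool ok = true;
    double ldet = 0.0;
    for (int j = 0; j < p && ok; ++j) {
      double d = A[j * p + j];
      for (int k = 0; k < j; ++k) d -= L[k * p + j] * L[k * p + j];
      if (d <= 0) { ok = false; break; }
      const double lj = std::sqrt(d);
      L[j * p + j] = lj;
      ldet += 2.0 * std::log(lj);
      for (int i = j + 1; i < p; ++i) {
        double s = A[j * p + i];
        for (int k = 0; k < j; ++k) s -= L[k * p + i] * L[k * p + j];
        L[j * p + i] = s / lj;
      }
    }
    if (!ok) { out[g] = R_NegInf; continue; }
    for (int i = 0; i < p; ++i) v[i] = Wtz(i, g) / s2 + sinv[i] * b0[i];
    // solve L y = v, then L^T m = y;  v' A^{-1} v = sum(m * v) via two solves
    for (int i = 0; i < p; ++i) {
      double s = v[i];
      for (int k = 0; k < i; ++k) s -= L[k * p + i] * m[k];
      m[i] = s / L[i * p + i];
    }
    double vAv = 0.0;
    for (int i = 0; i < p; ++i) vAv += m[i] * m[i];
    const double quad = zz / s2 + prior_quad - vAv;
    const double ld = ldet + ldetS + n * std::log(s2);
    out[g] = -0.5 * (n * std::log(2.0 * M_PI) + ld + quad);
  }
  return out;
}
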