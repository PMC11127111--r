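// Pruning likelihood for multistate / hidden-state speciation-extinction
// models (MuSSE / MuHiSSE / CTD). Along every branch the standard SSE ODE
// system over the K = S x H combined states,
//   dE_i/dt = mu - (lambda_i + mu + sum_j q_ij) E_i + lambda_i E_i^2
//             + sum_j q_ij E_j
//   dD_i/dt = -(lambda_i + mu + sum_j q_ij) D_i + 2 lambda_i E_i D_i
//             + sum_j q_ij D_j
// is integrated tipward-to-root with an adaptive Dormand-Prince RK45
// (rtol 1e-8 / atol 1e-10 by default). Tip conditions: D_i = rho for the
// combined states consistent with the observed tip state (all hidden
// levels), else 0; E_i = 1 - rho. At internal nodes D <- D_left * D_right
// * lambda. The root combines states with either uniform or observed-data
// (FitzJohn) weights, optionally conditioned on survival.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct SSEPars {
  vec lambda;   // K
  double mu;
  mat Q;        // K x K combined transition matrix, rows sum to 0
};

// y = [E (K), D (K)]; hand-rolled to keep the integrator allocation-free
inline void sse_deriv(const SSEPars& p, const double* y, double* dy) {
  const int K = p.lambda.n_elem;
  const double* lam = p.lambda.memptr();
  const double* Q = p.Q.memptr();  // column-major
  const double mu = p.mu;
  const double* E = y;
  const double* D = y + K;
  for (int i = 0; i < K; ++i) {
    dy[i] = mu - (lam[i] + mu) * E[i] + lam[i] * E[i] * E[i];
    dy[K + i] = (-(lam[i] + mu) + 2.0 * lam[i] * E[i]) * D[i];
  }
  for (int j = 0; j < K; ++j) {
    const double* Qj = Q + (size_t)j * K;
    const double Ej = E[j], Dj = D[j];
    for (int i = 0; i < K; ++i) {
      dy[i] += Qj[i] * Ej;
      dy[K + i] += Qj[i] * Dj;
    }
  }
}

// Dormand-Prince 5(4) with standard PI-free step control.
// Returns false on step-size underflow.
bool dopri45(const SSEPars& p, vec& y, double len, double rtol, double atol,
             int* n_clip) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100,
                      e7 = -1.0 / 40;
  if (len <= 0.0) return true;
  const int n = y.n_elem;
  const int K = n / 2;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      yt(n), y5(n);
  double* yp = y.memptr();
  double t = 0.0;
  double h = std::min(len, 0.1);
  const double hmin = len * 1e-12;
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) return false;
    if (t + h > len) h = len - t;
    sse_deriv(p, yp, k1.data());
    for (int i = 0; i < n; ++i) yt[i] = yp[i] + h * a21 * k1[i];
    sse_deriv(p, yt.data(), k2.data());
    for (int i = 0; i < n; ++i)
      yt[i] = yp[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sse_deriv(p, yt.data(), k3.data());
    for (int i = 0; i < n; ++i)
      yt[i] = yp[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sse_deriv(p, yt.data(), k4.data());
    for (int i = 0; i < n; ++i)
      yt[i] = yp[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                           a54 * k4[i]);
    sse_deriv(p, yt.data(), k5.data());
    for (int i = 0; i < n; ++i)
      yt[i] = yp[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                           a64 * k4[i] + a65 * k5[i]);
    sse_deriv(p, yt.data(), k6.data());
    for (int i = 0; i < n; ++i)
      y5[i] = yp[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                           b5 * k5[i] + b6 * k6[i]);
    sse_deriv(p, y5.data(), k7.data());
    double enorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::abs(yp[i]), std::abs(y5[i]));
      enorm = std::max(enorm, std::abs(err) / sc);
    }
    if (enorm <= 1.0) {
      t += h;
      // keep the state in its physical box
      for (int i = 0; i < K; ++i) {
        double Ei = y5[i], Di = y5[K + i];
        yp[i] = Ei < 0.0 ? 0.0 : (Ei > 1.0 ? 1.0 : Ei);
        if (Di < 0.0) {
          if (Di < -1e-12 && n_clip) ++(*n_clip);
          Di = 0.0;
        }
        yp[K + i] = Di;
      }
    }
    double fac = 0.9 * std::pow(std::max(enorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < hmin) return false;
  }
  return true;
}

}  // namespace

// edge: postorder edges (children before parents), 1-based ape numbering;
// tip_state: observed state 1..S per tip.
// [[Rcpp::export]]
Rcpp::List sse_loglik_cpp(const arma::imat& edge,
                          const arma::vec& edge_length, int n_tip,
                          const arma::ivec& tip_state, int S, int H,
                          const arma::vec& lambda, double mu,
                          const arma::mat& Q_comb, double rho,
                          bool root_obs_weights, bool condition,
                          double rtol, double atol) {
  const int K = S * H;
  const int n_nodes = edge.max();
  SSEPars pars{lambda, mu, Q_comb};
  mat E(K, n_nodes, fill::zeros), D(K, n_nodes, fill::zeros);
  ivec visits(n_nodes, fill::zeros);
  for (int i = 0; i < n_tip; ++i) {
    E.col(i).fill(1.0 - rho);
    const int s = tip_state(i) - 1;  // combined index = (s) * H + h
    for (int h = 0; h < H; ++h) D(s * H + h, i) = rho;
    visits(i) = 2;
  }
  int n_clip = 0;
  double logscale = 0.0;
  const int n_edge = edge.n_rows;
  for (int e = 0; e < n_edge; ++e) {
    const int par = edge(e, 0) - 1;
    const int ch = edge(e, 1) - 1;
    vec y(2 * K);
    y.head(K) = E.col(ch);
    y.tail(K) = D.col(ch);
    if (!dopri45(pars, y, edge_length(e), rtol, atol, &n_clip)) {
      return Rcpp::List::create(
          Rcpp::Named("loglik") = R_NegInf,
          Rcpp::Named("n_clip") = n_clip,
          Rcpp::Named("failed_edge") = e + 1);
    }
    if (visits(par) == 0) {
      E.col(par) = y.head(K);
      D.col(par) = y.tail(K);
    } else {
      // second daughter: average the (numerically near-identical) E
      // arrivals and form the node D with the speciation rate
      E.col(par) = 0.5 * (E.col(par) + y.head(K));
      D.col(par) = D.col(par) % y.tail(K) % lambda;
      double m = D.col(par).max();
      if (!(m > 0.0)) {
        return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                  Rcpp::Named("n_clip") = n_clip,
                                  Rcpp::Named("failed_edge") = -1);
      }
      D.col(par) /= m;
      logscale += std::log(m);
    }
    visits(par) += 1;
  }
  const int root = n_tip;  // ape root node = n_tip + 1
  vec Droot = D.col(root), Eroot = E.col(root);
  vec w(K);
  if (root_obs_weights) {
    double s = accu(Droot);
    if (!(s > 0.0)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                Rcpp::Named("n_clip") = n_clip,
                                Rcpp::Named("failed_edge") = -1);
    }
    w = Droot / s;
  } else {
    w.fill(1.0 / K);
  }
  double lik = dot(w, Droot);
  double ll = std::log(lik) + logscale;
  if (condition) {
    double cond = dot(w, lambda % square(1.0 - Eroot));
    if (cond > 0.0) ll -= std::log(cond);
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("n_clip") = n_clip,
                            Rcpp::Named("failed_edge") = 0);
}
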