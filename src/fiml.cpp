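// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <vector>

using namespace Rcpp;

// Casewise full-information Gaussian log-likelihood, grouped by missingness
// pattern. The implied model is
//   y_i ~ N(nu + lambda * eta_i, psi * lambda lambda' + Theta)
// with eta_i an observed structural predictor score (all zero for a pure
// measurement model with latent variance psi). Missing entries of y are NaN.
// Returns the NEGATIVE log-likelihood.
// [[Rcpp::export]]
double fiml_nll(const arma::mat& y, const arma::vec& eta, const arma::vec& nu,
                const arma::vec& lambda, const arma::mat& Theta, double psi) {
  const int n = y.n_rows, p = y.n_cols;
  arma::mat Sigma = psi * (lambda * lambda.t()) + Theta;
  Sigma = arma::symmatu(Sigma);   // guard against fp-level asymmetry

  // group rows by missing-data pattern (bitmask over p <= 30 variables)
  std::map<unsigned int, std::vector<int> > groups;
  for (int i = 0; i < n; ++i) {
    unsigned int key = 0;
    for (int j = 0; j < p; ++j)
      if (arma::is_finite(y(i, j))) key |= (1u << j);
    if (key != 0u) groups[key].push_back(i);
  }

  const double LOG2PI = std::log(2.0 * M_PI);
  double ll = 0.0;
  for (std::map<unsigned int, std::vector<int> >::const_iterator it = groups.begin();
       it != groups.end(); ++it) {
    unsigned int key = it->first;
    const std::vector<int>& rows = it->second;
    arma::uvec obs(p);
    int k = 0;
    for (int j = 0; j < p; ++j) if (key & (1u << j)) obs(k++) = j;
    obs.resize(k);

    arma::mat S = Sigma.submat(obs, obs);
    arma::mat L;
    if (!arma::chol(L, S, "lower")) return R_PosInf;  // not PD: reject step
    if (L.diag().min() < 1e-10 * (1.0 + L.diag().max()))
      return R_PosInf;                                // numerically singular
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));

    arma::vec nu_o = nu.elem(obs);
    arma::vec lam_o = lambda.elem(obs);
    const int m = (int)rows.size();
    arma::mat R(k, m);
    for (int r = 0; r < m; ++r) {
      int i = rows[r];
      for (int jj = 0; jj < k; ++jj)
        R(jj, r) = y(i, obs(jj)) - nu_o(jj) - lam_o(jj) * eta(i);
    }
    arma::mat Z = arma::solve(arma::trimatl(L), R, arma::solve_opts::fast);
    double quad = arma::accu(arma::square(Z));
    ll += -0.5 * (m * (k * LOG2PI + logdet) + quad);
  }
  return -ll;
}

// Dense Dijkstra all-pairs shortest path lengths. W is a symmetric
// nonnegative weight matrix; edge lengths are 1/w for w > 0, absent
// otherwise. Unreachable pairs get Inf; the diagonal is 0.
// [[Rcpp::export]]
arma::mat sp_dist(const arma::mat& W) {
  const int n = W.n_rows;
  arma::mat L(n, n);
  L.fill(arma::datum::inf);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0) L(i, j) = 1.0 / W(i, j);

  arma::mat D(n, n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    arma::vec d(n);
    d.fill(arma::datum::inf);
    d(s) = 0.0;
    std::fill(done.begin(), done.end(), 0);
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = arma::datum::inf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && d(v) < best) { best = d(v); u = v; }
      if (u < 0) break;
      done[u] = 1;
      for (int v = 0; v < n; ++v) {
        if (!done[v] && std::isfinite(L(u, v)) && d(u) + L(u, v) < d(v))
          d(v) = d(u) + L(u, v);
      }
    }
    D.row(s) = d.t();
  }
  D.diag().zeros();
  return D;
}

// Weighted local efficiency per node on a max-normalised weight matrix Wn:
//   E_loc(i) = (1/(k_i (k_i - 1))) * sum_{j != h in N(i)}
//              (Wn(i,j) * Wn(i,h) / d_jh(N_i))^(1/3)
// where d_jh(N_i) is the shortest path length between j and h within the
// subgraph induced by the neighbours of i (lengths 1/w). Nodes with fewer
// than two neighbours score 0; unreachable neighbour pairs contribute 0.
// [[Rcpp::export]]
arma::vec local_eff_w(const arma::mat& Wn) {
  const int n = Wn.n_rows;
  arma::vec out(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    arma::uvec nb = arma::find(Wn.row(i).t() > 0);
    const int k = (int)nb.n_elem;
    if (k < 2) continue;
    arma::mat sub = Wn.submat(nb, nb);
    arma::mat D = sp_dist(sub);
    double acc = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) {
        if (a == b || !std::isfinite(D(a, b)) || D(a, b) <= 0) continue;
        acc += std::cbrt(Wn(i, nb(a)) * Wn(i, nb(b)) / D(a, b));
      }
    out(i) = acc / (double)(k * (k - 1));
  }
  return out;
}
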