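// Dual solver for the soft-margin C-SVC: SMO with first-order (maximal
// violating pair) working-set selection, operating on a precomputed kernel
// matrix. Kernel evaluation stays in R; only the O(iter * n) inner loop and
// the leave-one-out retraining sweep of the grid search are compiled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// core SMO on a kernel matrix; y must be +1/-1. On exit alpha holds the
// box-constrained duals and b the intercept of
// decision(x) = sum_i alpha_i y_i K(x_i, x) + b. Returns iterations used.
// warm = true reuses the incoming alpha (must be box-feasible with
// sum(alpha * y) = 0) and recomputes the gradient from it.
static int smo_core(const arma::mat& K, const arma::vec& y, double C,
                    double tol, int max_iter, arma::vec& alpha, double& b,
                    bool warm = false) {
  const int n = K.n_rows;
  arma::vec G(n);
  if (warm) {
    G = y % (K * (alpha % y));
    G -= 1.0;
  } else {
    alpha.zeros(n);
    G.fill(-1.0);  // gradient of the dual objective at alpha = 0
  }

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: i maximizes -y*G over I_up, j minimizes over I_low
    int i = -1, j = -1;
    double Gmax = -arma::datum::inf, Gmin = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
  }

  // intercept from the KKT conditions: free SVs satisfy y_t f(x_t) = 1
  double bsum = 0.0; int nfree = 0;
  double up_max = -arma::datum::inf, lo_min = arma::datum::inf;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { bsum += v; ++nfree; }
    bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up) up_max = std::max(up_max, v);
    if (lo) lo_min = std::min(lo_min, v);
  }
  b = nfree > 0 ? bsum / nfree : (up_max + lo_min) / 2.0;
  return iter;
}

// [[Rcpp::export]]
List smo_solve(const arma::mat& K, const arma::vec& y, double C,
               double tol = 1e-3, int max_iter = 100000) {
  arma::vec alpha;
  double b = 0.0;
  int iter = smo_core(K, y, C, tol, max_iter, alpha, b);
  return List::create(_["alpha"] = alpha, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}

// Leave-one-out sweep for one pairwise classifier of the OVO grid search.
// Kpair: m x m kernel of the two classes' samples; yb: their +/-1 labels;
// Kcross: m x q kernel against the remaining samples (other classes), whose
// folds never change this pair's training set. Returns
//   dec_loo[s]  : decision for pair sample s from the model trained on the
//                 other m-1 pair samples,
//   dec_other[t]: decision for outside sample t from the full-pair model.
// alpha0 optionally warm-starts the full-pair solve (e.g. with the solution
// for the previous, smaller C on the grid's C-path, which stays feasible as
// the box grows); pass a zero-length vector to cold-start. The returned
// alpha can seed the next call.
// [[Rcpp::export]]
List pair_loo_decisions(const arma::mat& Kpair, const arma::vec& yb,
                        const arma::mat& Kcross, double C,
                        const arma::vec& alpha0,
                        double tol = 1e-3, int max_iter = 100000) {
  const int m = Kpair.n_rows;
  arma::vec alpha;
  double b = 0.0;

  if (alpha0.n_elem == (unsigned) m) {
    alpha = arma::clamp(alpha0, 0.0, C);
    // clamping cannot break feasibility here (alpha0 <= previous C <= C),
    // but guard against a violated equality constraint anyway
    if (std::abs(arma::dot(alpha, yb)) > 1e-9) alpha.zeros();
    smo_core(Kpair, yb, C, tol, max_iter, alpha, b, true);
  } else {
    smo_core(Kpair, yb, C, tol, max_iter, alpha, b);
  }
  arma::vec coef = alpha % yb;
  arma::vec dec_other = Kcross.t() * coef;
  dec_other += b;

  arma::vec dec_loo(m);
  arma::uvec all = arma::regspace<arma::uvec>(0, m - 1);
  for (int s = 0; s < m; ++s) {
    arma::uvec keep = arma::find(all != (unsigned) s);
    arma::mat Ks = Kpair.submat(keep, keep);
    arma::vec ys = yb.elem(keep);
    // warm start from the full-pair solution: drop alpha_s, restore the
    // equality constraint by shifting its weight onto same-class samples
    // with box slack (or off opposite-class samples)
    arma::vec as = alpha.elem(keep);
    double need = alpha[s];
    const int msub = m - 1;
    for (int t = 0; t < msub && need > 1e-12; ++t)
      if (ys[t] == yb[s] && as[t] < C) {
        double add = std::min(C - as[t], need);
        as[t] += add; need -= add;
      }
    for (int t = 0; t < msub && need > 1e-12; ++t)
      if (ys[t] != yb[s] && as[t] > 0) {
        double sub = std::min(as[t], need);
        as[t] -= sub; need -= sub;
      }
    double bs = 0.0;
    smo_core(Ks, ys, C, tol, max_iter, as, bs, true);
    arma::vec krow = Kpair.col(s);
    dec_loo[s] = arma::dot(krow.elem(keep), as % ys) + bs;
  }
  return List::create(_["dec_loo"] = dec_loo, _["dec_other"] = dec_other,
                      _["alpha"] = alpha);
}
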