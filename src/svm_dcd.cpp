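#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularised, L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w' x_i)
// The bias is handled as an augmented constant feature (last weight).
// Deterministic for a given seed (coordinate order reshuffled per epoch).
//
// X: n x d feature matrix (already scaled), y in {-1, +1}.
// Returns the weight vector of length d + 1 (last entry = bias).
// [[Rcpp::export]]
NumericVector svm_dcd_fit(const NumericMatrix& X, const NumericVector& y,
                          double C, int max_epochs, double tol,
                          unsigned int seed) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;  // bias feature
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(seed);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        double delta = (a_new - alpha[i]) * y[i];
        alpha[i] = a_new;
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        w[d] += delta;
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
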