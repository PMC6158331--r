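// Soft-margin RBF SVM trained by a max-violating-pair SMO on the dual.
// The kernel matrix is held in memory, which is fine at the training sizes
// this pipeline uses (a few thousand epochs at most); the solver meets the
// max-margin optimality conditions to tolerance `tol`, which is all the
// decision-function contract requires.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0;
  for (int k = 0; k < X.ncol(); ++k) {
    double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

}  // namespace

// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_iter) {
  int n = X.nrow();
  if (n > 6000) stop("training set too large for the in-memory kernel");

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = rbf(X, i, j, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = grad of dual
  int iter = 0;
  double m_val = 0, M_val = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: most violating pair on -y*G
    int i = -1, j = -1;
    m_val = -std::numeric_limits<double>::infinity();
    M_val = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > m_val) { m_val = v; i = t; }
      if (lo && v < M_val) { M_val = v; j = t; }
    }
    if (i < 0 || j < 0 || m_val - M_val < tol) break;

    double quad = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                  2.0 * K[(size_t)i * n + j];
    if (quad <= 0) quad = 1e-12;
    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
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
    double dai = (alpha[i] - old_ai) * y[i], daj = (alpha[j] - old_aj) * y[j];
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (K[(size_t)i * n + t] * dai + K[(size_t)j * n + t] * daj);
    }
  }

  // bias: average of y_i - u_i over free support vectors, else the midpoint
  // of the violating-pair bounds (both equal y - u on their index sets)
  double b = 0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -y[t] * G[t];  // -yG = y - u
      ++n_free;
    }
  }
  b = n_free ? b / n_free : 0.5 * (m_val + M_val);

  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > 1e-8) sv.push_back(t);
  IntegerVector sv_idx(sv.size());
  NumericVector coef(sv.size());
  for (size_t k = 0; k < sv.size(); ++k) {
    sv_idx[k] = sv[k] + 1;  // 1-based for R
    coef[k] = alpha[sv[k]] * y[sv[k]];
  }
  return List::create(_["sv_index"] = sv_idx, _["coef"] = coef, _["b"] = b,
                      _["iterations"] = iter);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix SV, NumericVector coef,
                               double b, double gamma, NumericMatrix X) {
  int n = X.nrow(), m = SV.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = b;
    for (int j = 0; j < m; ++j) {
      double d2 = 0;
      for (int k = 0; k < p; ++k) {
        double d = X(i, k) - SV(j, k);
        d2 += d * d;
      }
      s += coef[j] * std::exp(-gamma * d2);
    }
    out[i] = s;
  }
  return out;
}
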