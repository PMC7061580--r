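#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Moving-window smoothing: normalized convolution of x with `kernel`,
// reflective edge padding (mirror about the edge sample, edge excluded),
// output aligned so that length(out) == length(x).  The window is anchored
// with floor((w-1)/2) samples of left context.
// [[Rcpp::export(name = ".smooth_conv")]]
NumericVector smooth_conv(NumericVector x, NumericVector kernel) {
  const int n = x.size(), w = kernel.size();
  if (w < 1) stop("kernel must be non-empty");
  if (n < w) stop("input shorter than the smoothing window");
  const int L = (w - 1) / 2;        // left context
  const int R = w - 1 - L;          // right context
  std::vector<double> xp(n + w - 1);
  for (int i = 0; i < L; ++i) xp[i] = x[std::min(n - 1, L - i)];
  for (int i = 0; i < n; ++i) xp[L + i] = x[i];
  for (int i = 0; i < R; ++i) xp[L + n + i] = x[std::max(0, n - 2 - i)];
  double ksum = 0.0;
  for (int j = 0; j < w; ++j) ksum += kernel[j];
  if (ksum == 0.0) stop("kernel must have nonzero sum");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < w; ++j) acc += kernel[j] * xp[i + j];
    out[i] = acc / ksum;
  }
  return out;
}

static inline double rbf(const NumericMatrix &X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// Binary C-SVC with RBF kernel, solved by SMO with maximal-violating-pair
// working-set selection (the classical first-order rule).  y must be +1/-1.
// Returns alpha (box-constrained dual variables), rho (so the decision
// function is sum_i alpha_i y_i K(x_i, x) - rho) and the iteration count.
// [[Rcpp::export(name = ".svm_smo_train")]]
List svm_smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
                   double eps = 1e-3, int max_iter = 100000) {
  const int n = X.nrow();
  if (y.size() != n) stop("length(y) != nrow(X)");

  // Precompute the kernel matrix; training sets here are small (<= ~1000).
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) K(i, j) = K(j, i) = rbf(X, i, j, gamma);
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: i from I_up maximizing -y G, j from I_low
    // minimizing -y G
    int i = -1, j = -1;
    double Gmax = -INFINITY, Gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > Gmax)  { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = 1e-12;
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // rho from the KKT conditions (average over free SVs when any exist)
  double ub = INFINITY, lb = -INFINITY, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) { if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG); }
    else if (alpha[t] <= 0) { if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG); }
    else { sum_free += yG; ++nr_free; }
  }
  const double rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter);
}

// Decision values sum_i coef_i K(x_i, x) - rho for each row of Xnew, where
// coef_i = alpha_i * y_i over the training rows Xtrain.
// [[Rcpp::export(name = ".svm_rbf_decision")]]
NumericVector svm_rbf_decision(NumericMatrix Xtrain, NumericVector coef,
                               double rho, double gamma, NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), m = Xnew.nrow(), d = Xtrain.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      if (coef[i] == 0.0) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = Xtrain(i, k) - Xnew(q, k);
        s += diff * diff;
      }
      acc += coef[i] * std::exp(-gamma * s);
    }
    out[q] = acc - rho;
  }
  return out;
}
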