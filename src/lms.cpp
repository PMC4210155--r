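#include <Rcpp.h>
using namespace Rcpp;

// Sample-sequential (N)LMS identification of an FIR response.
//
// y(n) = sum_k h[k] x[n-k], e(n) = d(n) - y(n),
// h[k] += step * e(n) * x[n-k]  with  step = mu / (||x_n||^2 + eps)
// for the normalized variant, or a fixed step mu otherwise.
// One iteration is a full wrap-free pass over the record; the per-iteration
// MSE is the mean squared prediction error during that pass.
// [[Rcpp::export]]
List lms_core(NumericVector x, NumericVector d, int L, double mu,
              int iterations, bool normalized, double eps) {
  int N = x.size();
  if (d.size() != N) stop("x and d must have the same length");
  if (L < 1 || L > N) stop("filter length out of range");
  NumericVector h(L);
  NumericVector mse(iterations);
  const double* xp = REAL(x);
  const double* dp = REAL(d);
  double* hp = REAL(h);
  for (int it = 0; it < iterations; ++it) {
    double acc = 0.0;
    long cnt = 0;
    // running input power over the current tap window
    double pwr = 0.0;
    for (int k = 0; k < L - 1; ++k) pwr += xp[k] * xp[k];
    for (int n = L - 1; n < N; ++n) {
      pwr += xp[n] * xp[n];
      double y = 0.0;
      const double* xw = xp + n;  // x[n - k] = xw[-k]
      for (int k = 0; k < L; ++k) y += hp[k] * xw[-k];
      double e = dp[n] - y;
      double step = normalized ? mu / (pwr + eps) : mu;
      double se = step * e;
      for (int k = 0; k < L; ++k) hp[k] += se * xw[-k];
      acc += e * e;
      ++cnt;
      pwr -= xp[n - L + 1] * xp[n - L + 1];
    }
    mse[it] = acc / cnt;
    if (!R_finite(mse[it]))
      stop("LMS diverged at iteration %d (MSE not finite); reduce mu (= %g)",
           it + 1, mu);
  }
  return List::create(_["h"] = h, _["mse"] = mse);
}

// Causal FIR prediction y(n) = sum_k h[k] x[n-k] over the whole record
// (taps reaching before the record start are treated as zero input).
// [[Rcpp::export]]
NumericVector fir_predict(NumericVector h, NumericVector x) {
  int L = h.size(), N = x.size();
  NumericVector y(N);
  const double* xp = REAL(x);
  const double* hp = REAL(h);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    int kmax = n + 1 < L ? n + 1 : L;
    double acc = 0.0;
    for (int k = 0; k < kmax; ++k) acc += hp[k] * xp[n - k];
    yp[n] = acc;
  }
  return y;
}
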