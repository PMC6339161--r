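#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sample entropy (Richman & Moorman): -log(A/B) where B counts template
// pairs of length m within Chebyshev tolerance r and A the same for m+1.
// Self-matches excluded; pairs counted once (i < j).
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0.0) return NA_REAL;
  long long A = 0, B = 0;
  int lim = n - m;
  for (int i = 0; i < lim; ++i) {
    for (int j = i + 1; j < lim; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
        if (d > r) break;
      }
      if (d <= r) {
        ++B;
        double t = std::fabs(x[i + m] - x[j + m]);
        if (t <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Rosenstein average log-divergence curve: embed x (dimension emb, lag
// delay), find each point's nearest neighbour outside a Theiler window
// (ignoring numerically duplicate points closer than min_d2), and return
// mean log Euclidean distance after t = 0..tmax steps. The largest
// Lyapunov exponent is the slope of the returned curve.
// [[Rcpp::export]]
NumericVector rosenstein_divergence_cpp(NumericVector x, int emb, int delay,
                                        int tmax, int theiler,
                                        double min_d2 = 0.0) {
  int n = x.size();
  int M = n - (emb - 1) * delay;
  if (M < theiler + 2 || M <= tmax + 1) return NumericVector(0);
  std::vector<int> nn(M, -1);
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < emb; ++k) {
        double t = x[i + k * delay] - x[j + k * delay];
        d2 += t * t;
        if (d2 >= best) break;
      }
      if (d2 < best && d2 > min_d2) { best = d2; nn[i] = j; }
    }
  }
  NumericVector out(tmax + 1), cnt(tmax + 1);
  for (int i = 0; i < M; ++i) {
    int j = nn[i];
    if (j < 0) continue;
    int horizon = std::min(tmax, M - 1 - std::max(i, j));
    for (int t = 0; t <= horizon; ++t) {
      double d2 = 0.0;
      for (int k = 0; k < emb; ++k) {
        double dd = x[i + t + k * delay] - x[j + t + k * delay];
        d2 += dd * dd;
      }
      if (d2 > 0.0) { out[t] += 0.5 * std::log(d2); cnt[t] += 1.0; }
    }
  }
  for (int t = 0; t <= tmax; ++t) out[t] = cnt[t] > 0 ? out[t] / cnt[t] : NA_REAL;
  return out;
}
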