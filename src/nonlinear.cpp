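// Core O(N^2) nonlinear dynamics estimators. Chebyshev (max) norm is used
// for all delay embeddings, following the ApEn/SampEn conventions; the
// correlation integral shares it so K2 of periodic signals vanishes as the
// embedding grows.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ApEn = phi_m - phi_{m+1}; phi_m is the mean over i of the log fraction
// of length-m templates within r (Chebyshev, self-matches included). Both
// template lengths share one pair scan: a length-(m+1) match is a
// length-m match whose last coordinate also agrees.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int M1 = n - m + 1;       // templates of length m
  int M2 = n - m;           // templates of length m+1
  std::vector<int> cnt1(M1, 0), cnt2(M2, 0);
  for (int i = 0; i < M1; ++i) {
    cnt1[i] += 1;                                  // self-match, length m
    if (i < M2) cnt2[i] += 1;                      // self-match, length m+1
    for (int j = i + 1; j < M1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
        if (d > r) break;
      }
      if (d <= r) {
        ++cnt1[i]; ++cnt1[j];
        if (i < M2 && j < M2 && std::fabs(x[i + m] - x[j + m]) <= r) {
          ++cnt2[i]; ++cnt2[j];
        }
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < M1; ++i) phi1 += std::log((double)cnt1[i] / M1);
  for (int i = 0; i < M2; ++i) phi2 += std::log((double)cnt2[i] / M2);
  return phi1 / M1 - phi2 / M2;
}

// Richman-Moorman counts: B = matching template pairs of length m,
// A = of length m+1, i != j (self-matches excluded), ordered pairs counted
// once (i < j).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int M = n - m;  // templates of length m and m+1 both exist for i < M
  double A = 0.0, B = 0.0;
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Lempel-Ziv 1976 production complexity (Kaspar-Schuster algorithm).
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, u = 0, v = 1, w = 1, vmax = 1;
  while (true) {
    if (s[u + v - 1] == s[w + v - 1]) {
      ++v;
      if (w + v >= n) { ++c; break; }
    } else {
      if (v > vmax) vmax = v;
      ++u;
      if (u == w) {
        ++c;
        w += vmax;
        if (w > n - 1) break;
        u = 0; v = 1; vmax = 1;
      } else {
        v = 1;
      }
    }
  }
  return c;
}

// Correlation sums C_m(r) for m = 1..m_max over a log-spaced radius grid,
// Chebyshev norm, Theiler exclusion |i-j| <= w. Row m-1 holds C_m over rs.
// [[Rcpp::export]]
NumericMatrix corr_integral_cpp(NumericVector x, int m_max, int tau,
                                NumericVector rs, int w) {
  int n = x.size();
  int nr = rs.size();
  NumericMatrix C(m_max, nr);
  for (int m = 1; m <= m_max; ++m) {
    int M = n - (m - 1) * tau;
    if (M < 2) { for (int q = 0; q < nr; ++q) C(m - 1, q) = NA_REAL; continue; }
    std::vector<double> hist(nr, 0.0);
    double npairs = 0.0;
    for (int i = 0; i < M; ++i) {
      for (int j = i + w + 1; j < M; ++j) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double t = std::fabs(x[i + k * tau] - x[j + k * tau]);
          if (t > d) d = t;
        }
        npairs += 1.0;
        // first radius index with rs[idx] >= d
        int lo = std::lower_bound(rs.begin(), rs.end(), d) - rs.begin();
        if (lo < nr) hist[lo] += 1.0;
      }
    }
    double run = 0.0;
    for (int q = 0; q < nr; ++q) {
      run += hist[q];
      C(m - 1, q) = (npairs > 0.0) ? run / npairs : NA_REAL;
    }
  }
  return C;
}

// Rosenstein mean log-divergence curve. For each reference point the
// nearest neighbour outside the Theiler window is tracked for max_t steps.
// Returns max_t + 1 values (t = 0..max_t); counts gives valid pairs per t.
// [[Rcpp::export]]
List lyap_divergence_cpp(NumericVector x, int m, int tau, int w, int max_t) {
  int n = x.size();
  int M = n - (m - 1) * tau;
  NumericVector acc(max_t + 1, 0.0);
  IntegerVector cnt(max_t + 1, 0);
  int pairs = 0;
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= w) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k * tau] - x[j + k * tau]);
        if (t > d) d = t;
        if (d >= best) break;
      }
      if (d < best && d > 0.0) { best = d; bj = j; }
    }
    if (bj < 0) continue;
    ++pairs;
    for (int t = 0; t <= max_t; ++t) {
      if (i + t >= M || bj + t >= M) break;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + t + k * tau] - x[bj + t + k * tau]);
        if (dd > d) d = dd;
      }
      if (d > 0.0) {
        acc[t] += std::log(d);
        cnt[t] += 1;
      }
    }
  }
  for (int t = 0; t <= max_t; ++t) {
    acc[t] = (cnt[t] > 0) ? acc[t] / cnt[t] : NA_REAL;
  }
  return List::create(_["logdiv"] = acc, _["counts"] = cnt,
                      _["pairs"] = pairs);
}
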