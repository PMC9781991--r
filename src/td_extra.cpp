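#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy per column: -log(A/B) with A = template matches of length
// m+1, B = matches of length m, Chebyshev distance, tolerance r (absolute
// units). Self-matches excluded. Degenerate counts (A or B zero) are capped
// at the conventional upper bound -log(2 / ((N-m-1)(N-m))).
// [[Rcpp::export(name = ".sampen_mat")]]
NumericVector sampen_mat(NumericMatrix x, int m, NumericVector r) {
  int n = x.nrow(), k = x.ncol();
  NumericVector out(k);
  for (int c = 0; c < k; ++c) {
    double tol = r[c];
    long double A = 0, B = 0;
    int nm = n - m;
    for (int i = 0; i < nm; ++i) {
      for (int j = i + 1; j < nm; ++j) {
        double d = 0.0;
        bool ok = true;
        for (int l = 0; l < m; ++l) {
          double diff = std::fabs(x(i + l, c) - x(j + l, c));
          if (diff > d) d = diff;
          if (d > tol) { ok = false; break; }
        }
        if (!ok) continue;
        B += 1;
        if (i + m < n && j + m < n) {
          double diff = std::fabs(x(i + m, c) - x(j + m, c));
          if (diff <= tol && d <= tol) A += 1;
        }
      }
    }
    double cap = -std::log(2.0 / ((double)(n - m - 1) * (double)(n - m)));
    if (A <= 0 || B <= 0) {
      out[c] = cap;
    } else {
      double v = -std::log((double)(A / B));
      out[c] = (v > cap) ? cap : v;
    }
  }
  return out;
}

// Higuchi fractal dimension per column, k_max as given: slope of
// log(L(k)) vs log(1/k) over k = 1..k_max.
// [[Rcpp::export(name = ".higuchi_mat")]]
NumericVector higuchi_mat(NumericMatrix x, int kmax) {
  int n = x.nrow(), cols = x.ncol();
  NumericVector out(cols);
  for (int c = 0; c < cols; ++c) {
    std::vector<double> lx, ly;
    for (int k = 1; k <= kmax; ++k) {
      double Lk = 0.0;
      int used = 0;
      for (int m = 0; m < k; ++m) {
        int nm = (n - 1 - m) / k; // number of steps in this sub-series
        if (nm < 1) continue;
        double L = 0.0;
        for (int i = 1; i <= nm; ++i) {
          L += std::fabs(x(m + i * k, c) - x(m + (i - 1) * k, c));
        }
        // normalization to the original series length
        L = L * (double)(n - 1) / ((double)nm * (double)k) / (double)k;
        Lk += L;
        ++used;
      }
      if (used == 0) continue;
      Lk /= used;
      if (Lk > 0) {
        lx.push_back(std::log(1.0 / k));
        ly.push_back(std::log(Lk));
      }
    }
    // least-squares slope
    int np = lx.size();
    if (np < 2) { out[c] = 1.0; continue; }
    double mx = 0, my = 0;
    for (int i = 0; i < np; ++i) { mx += lx[i]; my += ly[i]; }
    mx /= np; my /= np;
    double sxy = 0, sxx = 0;
    for (int i = 0; i < np; ++i) {
      sxy += (lx[i] - mx) * (ly[i] - my);
      sxx += (lx[i] - mx) * (lx[i] - mx);
    }
    out[c] = sxy / sxx;
  }
  return out;
}
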