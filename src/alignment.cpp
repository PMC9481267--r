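#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Histogram bin index on nb equal-width bins spanning [lo, hi]; the top edge
// is closed so v == hi lands in the last bin. Degenerate range -> bin 0.
static inline int bin_of(double v, double lo, double hi, int nb) {
  if (hi <= lo) return 0;
  int b = (int)std::floor((v - lo) / (hi - lo) * nb);
  if (b < 0) b = 0;
  if (b >= nb) b = nb - 1;
  return b;
}

// MI (nats) from paired bin indices. Joint counts are accumulated by sorting
// the <= n occupied cell codes instead of touching an nb x nb array.
static double mi_from_bins(const std::vector<int>& xb,
                           const std::vector<int>& yb,
                           const std::vector<int>& cx,
                           const std::vector<int>& cy,
                           int nb) {
  const int n = (int)xb.size();
  std::vector<long long> codes(n);
  for (int i = 0; i < n; ++i)
    codes[i] = (long long)xb[i] * nb + yb[i];
  std::sort(codes.begin(), codes.end());
  const double N = (double)n;
  double mi = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && codes[j] == codes[i]) ++j;
    const double cnt = (double)(j - i);
    const int bx = (int)(codes[i] / nb);
    const int by = (int)(codes[i] % nb);
    mi += (cnt / N) * std::log(cnt * N / ((double)cx[bx] * (double)cy[by]));
    i = j;
  }
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double mi_hist2d_cpp(NumericVector x, NumericVector y, int n_bins) {
  const int n = x.size();
  double xlo = x[0], xhi = x[0], ylo = y[0], yhi = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xlo) xlo = x[i];
    if (x[i] > xhi) xhi = x[i];
    if (y[i] < ylo) ylo = y[i];
    if (y[i] > yhi) yhi = y[i];
  }
  std::vector<int> xb(n), yb(n), cx(n_bins, 0), cy(n_bins, 0);
  for (int i = 0; i < n; ++i) {
    xb[i] = bin_of(x[i], xlo, xhi, n_bins);
    yb[i] = bin_of(y[i], ylo, yhi, n_bins);
    cx[xb[i]]++;
    cy[yb[i]]++;
  }
  return mi_from_bins(xb, yb, cx, cy, n_bins);
}

// MI against the reference for every left pad 0..(len(ref) - len(values)).
// The padded signal's histogram range is fixed across pads (zeros plus the
// original values), so per-sample bins are precomputed once.
// [[Rcpp::export]]
NumericVector pad_mi_profile_cpp(NumericVector values, NumericVector reference,
                                 int n_bins) {
  const int n = values.size();
  const int L = reference.size();
  const int P = L - n;
  if (P < 0) stop("trial longer than reference");

  double vlo = 0.0, vhi = 0.0;
  for (int i = 0; i < n; ++i) {
    if (values[i] < vlo) vlo = values[i];
    if (values[i] > vhi) vhi = values[i];
  }
  double rlo = reference[0], rhi = reference[0];
  for (int i = 1; i < L; ++i) {
    if (reference[i] < rlo) rlo = reference[i];
    if (reference[i] > rhi) rhi = reference[i];
  }

  const int zbin = bin_of(0.0, vlo, vhi, n_bins);
  std::vector<int> vbin(n), yb(L), cy(n_bins, 0);
  for (int i = 0; i < n; ++i) vbin[i] = bin_of(values[i], vlo, vhi, n_bins);
  for (int i = 0; i < L; ++i) {
    yb[i] = bin_of(reference[i], rlo, rhi, n_bins);
    cy[yb[i]]++;
  }

  // x marginal is the same multiset for every pad
  std::vector<int> cx(n_bins, 0);
  cx[zbin] += P;
  for (int i = 0; i < n; ++i) cx[vbin[i]]++;

  NumericVector out(P + 1);
  std::vector<int> xb(L);
  for (int left = 0; left <= P; ++left) {
    for (int t = 0; t < L; ++t) {
      if (t < left || t >= left + n)
        xb[t] = zbin;
      else
        xb[t] = vbin[t - left];
    }
    out[left] = mi_from_bins(xb, yb, cx, cy, n_bins);
  }
  return out;
}
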