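#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Map a template distance d to the smallest grid index k (0-based) with
// radii[k] >= d, or n when d exceeds r_max (overflow bin). The arithmetic
// guess from the uniform spacing is verified against neighbouring radii so
// that representable boundary distances (d == radii[k]) land exactly where
// the <= match convention requires.
static inline R_xlen_t bin_index(double d, const double *radii, R_xlen_t n,
                                 double rmin, double step) {
  double g = std::ceil((d - rmin) / step);
  R_xlen_t k = (g < 0.0) ? 0 : (g > (double)n ? n : (R_xlen_t)g);
  while (k > 0 && radii[k - 1] >= d) --k;
  while (k < n && radii[k] < d) ++k;
  return k;
}

// One pass over all unordered template pairs, histogramming the
// m-dimensional and (m+1)-dimensional Chebyshev template distances into
// the threshold grid. Per-bin counts for bins 0..n-1 plus an overflow bin
// at n (distances > r_max) are returned; cumulative sums give the match
// count at every radius simultaneously.
//
// limit_m / limit_m1: number of template start positions used for the
// m- and (m+1)-dimensional sums (they coincide under the Richman-Moorman
// convention and differ under the literal per-dimension convention).
// [[Rcpp::export]]
List ncm_pair_histogram(NumericVector x, int m, int tau, NumericVector radii,
                        int limit_m, int limit_m1) {
  const R_xlen_t n = radii.size();
  const double rmin = radii[0];
  const double step = (n > 1) ? (radii[n - 1] - radii[0]) / (double)(n - 1)
                              : 1.0;
  const double *rr = REAL(radii);
  const double *u = REAL(x);

  NumericVector hist_m(n + 1), hist_m1(n + 1);
  double *hm = REAL(hist_m);
  double *hm1 = REAL(hist_m1);

  for (int i = 0; i < limit_m; ++i) {
    for (int j = i + 1; j < limit_m; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(u[i + k * tau] - u[j + k * tau]);
        if (d > dm) dm = d;
      }
      hm[bin_index(dm, rr, n, rmin, step)] += 1.0;
      if (j < limit_m1) {
        double d = std::fabs(u[i + m * tau] - u[j + m * tau]);
        double dm1 = (d > dm) ? d : dm;
        hm1[bin_index(dm1, rr, n, rmin, step)] += 1.0;
      }
    }
  }

  return List::create(_["hist_m"] = hist_m, _["hist_m1"] = hist_m1);
}
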