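// Dip-type unimodality statistic: the L-infinity distance between the
// empirical CDF and the nearest convex-concave (i.e. unimodal-density) CDF,
// minimised over the mode position. Calibrated against the uniform null by
// Monte Carlo, which is the construction of Hartigan's dip test.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

// prefix deviations from the greatest convex minorant, left-to-right.
// x sorted ascending; flo[i] = i/n, fhi[i] = (i+1)/n.
// dev[k] = max_{j<=k} ( fhi[j] - gcm_{0..k}(x_j) ), nondecreasing in k.
void prefix_convex_dev(const std::vector<double>& x,
                       const std::vector<double>& flo,
                       const std::vector<double>& fhi,
                       std::vector<double>& dev) {
  int n = x.size();
  std::vector<int> hull;
  hull.reserve(n);
  double cur = 0.0;
  for (int k = 0; k < n; ++k) {
    // pop hull vertices that lie above the chord to the new point
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * (flo[k] - flo[a]) -
                     (x[k] - x[a]) * (flo[b] - flo[a]);
      if (cross <= 0.0) hull.pop_back();
      else break;
    }
    // deviation of interior points against the new closing segment
    if (!hull.empty()) {
      int a = hull.back();
      double dx = x[k] - x[a];
      for (int j = a + 1; j < k; ++j) {
        double g = dx > 0 ? flo[a] + (flo[k] - flo[a]) * (x[j] - x[a]) / dx
                          : flo[a];
        double d = fhi[j] - g;
        if (d > cur) cur = d;
      }
      double d = fhi[k] - flo[k];
      if (d > cur) cur = d;
    }
    hull.push_back(k);
    dev[k] = cur;
  }
}

double dip_stat_sorted(std::vector<double> x) {
  int n = x.size();
  if (n < 3) return 0.0;
  std::vector<double> flo(n), fhi(n);
  for (int i = 0; i < n; ++i) {
    flo[i] = (double)i / n;
    fhi[i] = (double)(i + 1) / n;
  }
  std::vector<double> devL(n, 0.0), devR(n, 0.0);
  prefix_convex_dev(x, flo, fhi, devL);
  // right side: reflect; concave majorant of F == convex minorant of the
  // reflected complement
  std::vector<double> xr(n), flor(n), fhir(n);
  for (int i = 0; i < n; ++i) {
    xr[i] = -x[n - 1 - i];
    flor[i] = (double)i / n;       // 1 - fhi reflected
    fhir[i] = (double)(i + 1) / n; // 1 - flo reflected
  }
  std::vector<double> devRr(n, 0.0);
  prefix_convex_dev(xr, flor, fhir, devRr);
  for (int i = 0; i < n; ++i) devR[i] = devRr[n - 1 - i];
  double best = R_PosInf;
  for (int k = 0; k < n; ++k) {
    double m = std::max(devL[k], devR[k]);
    if (m < best) best = m;
  }
  return best;
}

} // namespace

// [[Rcpp::export(name = ".dip_stat")]]
double dip_stat(NumericVector x) {
  std::vector<double> v = as<std::vector<double> >(x);
  std::sort(v.begin(), v.end());
  return dip_stat_sorted(v);
}

// [[Rcpp::export(name = ".dip_null_quantiles")]]
NumericVector dip_null(int n, int n_boot, double seed) {
  std::mt19937_64 gen((uint64_t)seed ^ 0xa5a5a5a5deadbeefULL);
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    std::vector<double> u(n);
    for (int i = 0; i < n; ++i)
      u[i] = ((gen() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
    std::sort(u.begin(), u.end());
    out[b] = dip_stat_sorted(u);
  }
  return out;
}
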