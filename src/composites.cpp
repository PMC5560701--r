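#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Type-7 (linear interpolation) quantile of a sorted vector.
static double quantile7(const std::vector<double> &x, double p) {
  int n = x.size();
  if (n == 1) return x[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

static double median_of(std::vector<double> x) {
  std::sort(x.begin(), x.end());
  int n = x.size();
  if (n % 2 == 1) return x[n / 2];
  return (x[n / 2 - 1] + x[n / 2]) / 2.0;
}

// Per-pixel spectral-temporal composites. Inputs: band matrices
// (pixels x dates) and a validity mask. Output: pixels x 13 matrix
// (med.{4}, minNDVI.{4}, maxNDVI.{4}, n_valid). Pixels with fewer than
// min_valid clear observations, or with no computable NDVI, are all-NA
// (n_valid still reported).
// [[Rcpp::export]]
NumericMatrix composites_cpp(NumericMatrix red, NumericMatrix nir,
                             NumericMatrix swir1, NumericMatrix swir2,
                             LogicalMatrix valid, int min_valid) {
  int npix = red.nrow(), ndate = red.ncol();
  NumericMatrix out(npix, 13);
  std::fill(out.begin(), out.end(), NA_REAL);
  const NumericMatrix *bands[4] = {&red, &nir, &swir1, &swir2};

  std::vector<int> idx;
  std::vector<double> vals, ndvi;
  std::vector<int> ndvi_idx;

  for (int i = 0; i < npix; ++i) {
    idx.clear();
    for (int d = 0; d < ndate; ++d)
      if (valid(i, d) == TRUE) idx.push_back(d);
    int nv = idx.size();
    out(i, 12) = nv;
    if (nv < min_valid || nv == 0) continue;

    // medians per band
    double med[4];
    for (int b = 0; b < 4; ++b) {
      vals.clear();
      for (size_t k = 0; k < idx.size(); ++k)
        vals.push_back((*bands[b])(i, idx[k]));
      med[b] = median_of(vals);
    }

    // NDVI of valid observations; zero-sum denominators excluded from
    // decile selection but their dates still counted in the medians above
    ndvi.clear(); ndvi_idx.clear();
    for (size_t k = 0; k < idx.size(); ++k) {
      double r = red(i, idx[k]), n = nir(i, idx[k]);
      double s = r + n;
      if (s > 0) {
        ndvi.push_back((n - r) / s);
        ndvi_idx.push_back(idx[k]);
      }
    }
    if (ndvi.empty()) continue; // no computable NDVI -> pixel stays nodata

    std::vector<double> sorted(ndvi);
    std::sort(sorted.begin(), sorted.end());
    double q10 = quantile7(sorted, 0.10);
    double q90 = quantile7(sorted, 0.90);

    double losum[4] = {0, 0, 0, 0}, hisum[4] = {0, 0, 0, 0};
    int nlo = 0, nhi = 0;
    for (size_t k = 0; k < ndvi.size(); ++k) {
      if (ndvi[k] <= q10) {
        ++nlo;
        for (int b = 0; b < 4; ++b) losum[b] += (*bands[b])(i, ndvi_idx[k]);
      }
      if (ndvi[k] >= q90) {
        ++nhi;
        for (int b = 0; b < 4; ++b) hisum[b] += (*bands[b])(i, ndvi_idx[k]);
      }
    }
    for (int b = 0; b < 4; ++b) {
      out(i, b) = med[b];
      out(i, 4 + b) = losum[b] / nlo;
      out(i, 8 + b) = hisum[b] / nhi;
    }
  }
  return out;
}
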