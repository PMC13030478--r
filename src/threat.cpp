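#include <Rcpp.h>
using namespace Rcpp;

// Distance-decayed threat influence field.
// For every cell x: max over source cells y of r_y * i(d_xy), with
//   linear:      i(d) = max(0, 1 - d/dmax)
//   exponential: i(d) = exp(-(2.99/dmax) * d), 0 beyond dmax
// Distances are Euclidean between cell centers, in km (cellsize_km per cell).
// Sweep: for each nonzero source cell, update its dmax-neighbourhood with a
// precomputed kernel; O(#sources * kernel size).
// [[Rcpp::export]]
NumericMatrix threat_sweep(NumericMatrix source, double cellsize_km,
                           double dmax_km, int exponential) {
  int nr = source.nrow(), nc = source.ncol();
  int R = (int)std::floor(dmax_km / cellsize_km + 1e-9);
  int K = 2 * R + 1;
  NumericMatrix kern(K, K);
  for (int di = -R; di <= R; ++di) {
    for (int dj = -R; dj <= R; ++dj) {
      double d = cellsize_km * std::sqrt((double)(di * di + dj * dj));
      double v;
      if (d > dmax_km) v = 0.0;
      else if (exponential) v = std::exp(-(2.99 / dmax_km) * d);
      else v = 1.0 - d / dmax_km;
      if (v < 0) v = 0;
      kern(di + R, dj + R) = v;
    }
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double r = source(i, j);
      if (!(r > 0)) continue;  // NA or zero: no influence
      int i0 = std::max(0, i - R), i1 = std::min(nr - 1, i + R);
      int j0 = std::max(0, j - R), j1 = std::min(nc - 1, j + R);
      for (int ii = i0; ii <= i1; ++ii) {
        for (int jj = j0; jj <= j1; ++jj) {
          double v = r * kern(ii - i + R, jj - j + R);
          if (v > out(ii, jj)) out(ii, jj) = v;
        }
      }
    }
  }
  return out;
}
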