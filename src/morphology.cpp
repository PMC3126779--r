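#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Grayscale erosion/dilation with an arbitrary footprint (odd-sided logical
// matrix). Out-of-bounds pixels are ignored, i.e. padded with the operation's
// neutral element: +Inf for erosion ("white"), -Inf for dilation ("black").
// Binary masks are handled as 0/1 rasters by the same code path.

static NumericMatrix rank_extreme(const NumericMatrix& x,
                                  const LogicalMatrix& fp,
                                  bool take_min) {
  const int nr = x.nrow(), nc = x.ncol();
  const int fr = fp.nrow(), fc = fp.ncol();
  const int cr = fr / 2, cc = fc / 2; // odd sides enforced by caller
  // precompute active offsets
  std::vector<int> dr, dc;
  dr.reserve(fr * fc); dc.reserve(fr * fc);
  for (int i = 0; i < fr; ++i)
    for (int j = 0; j < fc; ++j)
      if (fp(i, j)) { dr.push_back(i - cr); dc.push_back(j - cc); }
  NumericMatrix out(nr, nc);
  const int K = (int)dr.size();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = take_min ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = x(ii, jj);
        if (take_min) { if (v < acc) acc = v; }
        else          { if (v > acc) acc = v; }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".gray_erode_cpp")]]
NumericMatrix gray_erode_cpp(NumericMatrix x, LogicalMatrix fp) {
  return rank_extreme(x, fp, true);
}

// [[Rcpp::export(name = ".gray_dilate_cpp")]]
NumericMatrix gray_dilate_cpp(NumericMatrix x, LogicalMatrix fp) {
  return rank_extreme(x, fp, false);
}

// Rectangular median filter. Windows truncate at the raster border. With
// sub-sample ratio s > 1 the median is evaluated on an s-strided grid only
// and the remaining pixels copy their nearest evaluated pixel (ties toward
// the lower index).
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix x, int width, int height,
                                int sub) {
  const int nr = x.nrow(), nc = x.ncol();
  const int hr = height / 2, hc = width / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)width * height);

  // nearest evaluated index for every row/col (ties toward the lower index)
  auto snap = [sub](int i, int n) {
    if (sub == 1) return i;
    const int last = ((n - 1) / sub) * sub;
    const int lo = (i / sub) * sub;
    const int hi = std::min(lo + sub, last);
    return (i - lo <= hi - i) ? lo : hi;
  };
  std::vector<int> snap_r(nr), snap_c(nc);
  for (int i = 0; i < nr; ++i) snap_r[i] = snap(i, nr);
  for (int j = 0; j < nc; ++j) snap_c[j] = snap(j, nc);

  for (int j = 0; j < nc; j += sub) {
    for (int i = 0; i < nr; i += sub) {
      buf.clear();
      const int r0 = std::max(0, i - hr), r1 = std::min(nr - 1, i + hr);
      const int c0 = std::max(0, j - hc), c1 = std::min(nc - 1, j + hc);
      for (int jj = c0; jj <= c1; ++jj)
        for (int ii = r0; ii <= r1; ++ii)
          buf.push_back(x(ii, jj));
      const size_t n = buf.size();
      const size_t m = n / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  if (sub > 1) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        out(i, j) = out(snap_r[i], snap_c[j]);
  }
  return out;
}

// Connected-component labeling of a 0/1 raster, 4- or 8-connectivity.
// Labels are assigned in column-major discovery order starting at 1.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int K = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (x(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int k = 0; k < K; ++k) {
          const int qi = pi + dr8[k], qj = pj + dc8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (x(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
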