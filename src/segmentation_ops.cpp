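// Per-frame image kernels: exact clipped-window local mean (integral image)
// and disc-shaped binary erosion/dilation. These run on every video frame,
// so they are compiled.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_local_mean(const NumericMatrix& x, const int r) {
  const int nr = x.nrow(), nc = x.ncol();
  // integral image with a zero first row/column
  std::vector<double> ii((nr + 1) * (nc + 1), 0.0);
  const int inr = nr + 1;
  for (int j = 0; j < nc; ++j) {
    double colsum = 0.0;
    for (int i = 0; i < nr; ++i) {
      colsum += x(i, j);
      ii[(j + 1) * inr + (i + 1)] = ii[j * inr + (i + 1)] + colsum;
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int c1 = std::max(j - r, 0), c2 = std::min(j + r, nc - 1);
    for (int i = 0; i < nr; ++i) {
      const int r1 = std::max(i - r, 0), r2 = std::min(i + r, nr - 1);
      const double s = ii[(c2 + 1) * inr + (r2 + 1)] - ii[c1 * inr + (r2 + 1)]
        - ii[(c2 + 1) * inr + r1] + ii[c1 * inr + r1];
      out(i, j) = s / ((r2 - r1 + 1) * (c2 - c1 + 1));
    }
  }
  return out;
}

static std::vector<std::pair<int, int>> disc(const int r) {
  std::vector<std::pair<int, int>> off;
  for (int dv = -r; dv <= r; ++dv)
    for (int du = -r; du <= r; ++du)
      if (dv * dv + du * du <= r * r) off.push_back({dv, du});
  return off;
}

// Erosion: pixel survives iff every disc neighbour (inside the image) is
// foreground; pixels beyond the border count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_binary_erode(const LogicalMatrix& x, const int r) {
  const int nr = x.nrow(), nc = x.ncol();
  const auto off = disc(r);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j)) { out(i, j) = FALSE; continue; }
      bool keep = true;
      for (const auto& o : off) {
        const int ii2 = i + o.first, jj = j + o.second;
        if (ii2 < 0 || ii2 >= nr || jj < 0 || jj >= nc || !x(ii2, jj)) {
          keep = false; break;
        }
      }
      out(i, j) = keep;
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_binary_dilate(const LogicalMatrix& x, const int r) {
  const int nr = x.nrow(), nc = x.ncol();
  const auto off = disc(r);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j)) continue;
      for (const auto& o : off) {
        const int ii2 = i + o.first, jj = j + o.second;
        if (ii2 >= 0 && ii2 < nr && jj >= 0 && jj < nc) out(ii2, jj) = TRUE;
      }
    }
  return out;
}
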