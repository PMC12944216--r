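#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion/dilation with an arbitrary (possibly non-flat) structuring
// element given as offset lists (dy, dx) and heights h. Edge handling: offsets
// falling outside the image are ignored (flat-extension semantics adequate for
// background estimation on bounded images).
static NumericMatrix morph(const NumericMatrix& img,
                           const IntegerVector& dy, const IntegerVector& dx,
                           const NumericVector& h, bool erode) {
  int m = img.nrow(), n = img.ncol(), K = dy.size();
  NumericMatrix out(m, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + dy[k], jj = j + dx[k];
        if (ii < 0 || ii >= m || jj < 0 || jj >= n) continue;
        double v = erode ? img(ii, jj) - h[k] : img(ii, jj) + h[k];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Rolling-ball background: grayscale opening with a ball-shaped structuring
// element of the given radius (pixels). Returns the background estimate.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball(NumericMatrix img, double radius) {
  int r = (int)std::floor(radius);
  std::vector<int> dyv, dxv; std::vector<double> hv;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        dyv.push_back(a); dxv.push_back(b);
        hv.push_back(std::sqrt(radius * radius - d2) - radius); // <= 0
      }
    }
  IntegerVector dy(dyv.begin(), dyv.end()), dx(dxv.begin(), dxv.end());
  NumericVector h(hv.begin(), hv.end());
  NumericMatrix er = morph(img, dy, dx, h, true);
  return morph(er, dy, dx, h, false);
}

// Median filter over a disk neighborhood of (possibly fractional) radius.
// Edge pixels use the in-bounds part of the disk.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(NumericMatrix img, double radius) {
  int r = (int)std::floor(radius);
  std::vector<int> dyv, dxv;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)a * a + (double)b * b <= radius * radius) {
        dyv.push_back(a); dxv.push_back(b);
      }
  int m = img.nrow(), n = img.ncol(), K = (int)dyv.size();
  NumericMatrix out(m, n);
  std::vector<double> buf; buf.reserve(K);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      buf.clear();
      for (int k = 0; k < K; ++k) {
        int ii = i + dyv[k], jj = j + dxv[k];
        if (ii < 0 || ii >= m || jj < 0 || jj >= n) continue;
        buf.push_back(img(ii, jj));
      }
      size_t sz = buf.size(), mid = sz / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (sz % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  return out;
}

// Connected-component labeling of nonzero pixels, 4- or 8-connectivity.
// Labels are assigned in raster-scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int m = mask.nrow(), n = mask.ncol();
  IntegerMatrix lab(m, n);
  int ndir = (connectivity == 8) ? 8 : 4;
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second; q.pop();
        for (int d = 0; d < ndir; ++d) {
          int ii = ci + dy8[d], jj = cj + dx8[d];
          if (ii < 0 || ii >= m || jj < 0 || jj >= n) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

// Perimeter of each labeled component, counted as the number of pixel edges
// between the component and anything else (background or another label).
// A digital s x s square has perimeter 4s under this count.
// [[Rcpp::export]]
NumericVector cpp_component_perimeter(IntegerMatrix lab, int nlab) {
  int m = lab.nrow(), n = lab.ncol();
  NumericVector per(nlab);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      if (i == 0 || lab(i - 1, j) != l) per[l - 1] += 1;
      if (i == m - 1 || lab(i + 1, j) != l) per[l - 1] += 1;
      if (j == 0 || lab(i, j - 1) != l) per[l - 1] += 1;
      if (j == n - 1 || lab(i, j + 1) != l) per[l - 1] += 1;
    }
  return per;
}

// Frame-wise 2D convolution of an m x n x t array with a small kernel,
// replicate edge handling. Kernel is flipped (true convolution); symmetric
// kernels are unaffected.
// [[Rcpp::export]]
NumericVector cpp_conv2_frames(NumericVector arr, IntegerVector dims,
                               NumericMatrix kernel) {
  int m = dims[0], n = dims[1], t = dims[2];
  int kr = (kernel.nrow() - 1) / 2, kc = (kernel.ncol() - 1) / 2;
  NumericVector out(arr.size());
  const double* in = arr.begin();
  double* o = out.begin();
  for (int f = 0; f < t; ++f) {
    const double* fr = in + (size_t)f * m * n;
    double* fo = o + (size_t)f * m * n;
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < m; ++i) {
        double acc = 0;
        for (int b = -kc; b <= kc; ++b) {
          int jj = j + b;
          if (jj < 0) jj = 0; else if (jj >= n) jj = n - 1;
          for (int a = -kr; a <= kr; ++a) {
            int ii = i + a;
            if (ii < 0) ii = 0; else if (ii >= m) ii = m - 1;
            acc += kernel(kr - a, kc - b) * fr[(size_t)jj * m + ii];
          }
        }
        fo[(size_t)j * m + i] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
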