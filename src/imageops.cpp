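#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Reflective (mirror-without-repeat) index into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// Grayscale erosion with a non-flat structuring element.
// dx, dy: integer offsets of SE support; h: SE heights at those offsets.
// erosion(I)(p) = min_k { I(p + off_k) - h_k }, reflective borders.
// [[Rcpp::export]]
NumericMatrix cpp_erode_nonflat(const NumericMatrix& img,
                                const IntegerVector& dx,
                                const IntegerVector& dy,
                                const NumericVector& h) {
  int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int k = 0; k < K; ++k) {
    int ox = dx[k], oy = dy[k];
    double hk = h[k];
    for (int j = 0; j < nc; ++j) {
      int jj = reflect_idx(j + ox, nc);
      for (int i = 0; i < nr; ++i) {
        int ii = reflect_idx(i + oy, nr);
        double v = img(ii, jj) - hk;
        if (v < out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// Grayscale dilation with a non-flat SE (reflected SE, so that
// dilate(erode(I)) is the opening by the same element).
// [[Rcpp::export]]
NumericMatrix cpp_dilate_nonflat(const NumericMatrix& img,
                                 const IntegerVector& dx,
                                 const IntegerVector& dy,
                                 const NumericVector& h) {
  int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_NegInf);
  for (int k = 0; k < K; ++k) {
    int ox = -dx[k], oy = -dy[k];
    double hk = h[k];
    for (int j = 0; j < nc; ++j) {
      int jj = reflect_idx(j + ox, nc);
      for (int i = 0; i < nr; ++i) {
        int ii = reflect_idx(i + oy, nr);
        double v = img(ii, jj) + hk;
        if (v > out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask (BFS flood fill).
// Returns an integer matrix of labels, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      lab(i0, j0) = next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        int i = q.front().first, j = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Separable convolution with a 1-D kernel along rows then columns,
// reflective borders. Kernel length must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(const NumericMatrix& img,
                               const NumericVector& kernel) {
  int nr = img.nrow(), nc = img.ncol(), K = kernel.size();
  int half = K / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns of the matrix (y direction)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        int ii = reflect_idx(i + k - half, nr);
        acc += img(ii, j) * kernel[k];
      }
      tmp(i, j) = acc;
    }
  }
  // along rows (x direction)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        int jj = reflect_idx(j + k - half, nc);
        acc += tmp(i, jj) * kernel[k];
      }
      out(i, j) = acc;
    }
  }
  return out;
}
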