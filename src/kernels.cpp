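#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact 3x3 median of a single slice with edge replication.
// Used by the denoising step; exactness matters because the output is
// compared against an ordered-statistic reference in the test suite.
static inline void sort2(double &a, double &b) {
  double lo = a < b ? a : b, hi = a < b ? b : a;
  a = lo; b = hi;
}

// exact median of 9 via a 19-exchange sorting network
static inline double median9(double p0, double p1, double p2, double p3,
                             double p4, double p5, double p6, double p7,
                             double p8) {
  sort2(p1, p2); sort2(p4, p5); sort2(p7, p8);
  sort2(p0, p1); sort2(p3, p4); sort2(p6, p7);
  sort2(p1, p2); sort2(p4, p5); sort2(p7, p8);
  sort2(p0, p3); sort2(p5, p8); sort2(p4, p7);
  sort2(p3, p6); sort2(p1, p4); sort2(p2, p5);
  sort2(p4, p7); sort2(p4, p2); sort2(p6, p4);
  sort2(p4, p2);
  return p4;
}

// [[Rcpp::export(name = ".median3x3_cpp")]]
NumericMatrix median3x3_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double *px = x.begin();
  double *po = out.begin();
  for (int j = 0; j < nc; ++j) {
    const int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
    const double *cm = px + (size_t)jm * nr;
    const double *cc = px + (size_t)j * nr;
    const double *cp = px + (size_t)jp * nr;
    double *oc = po + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
      oc[i] = median9(cm[im], cm[i], cm[ip],
                      cc[im], cc[i], cc[ip],
                      cp[im], cp[i], cp[ip]);
    }
  }
  return out;
}

// im2col for a 3x3 "same" convolution: x is an (H, W, C) array
// (column-major), output is (H*W, 9*C) with column c*9 + (dx+1)*3 + (dy+1)
// holding the source pixel shifted by (dy, dx) in {-1,0,1}^2 (zeros outside
// the frame). Matches matrix(W, 9*C, Cout) flattening of a (3,3,C,Cout)
// kernel array, so conv = im2col(x) %*% matrix(W).
// [[Rcpp::export(name = ".im2col3x3_cpp")]]
NumericMatrix im2col3x3_cpp(NumericVector x, int H, int W, int C) {
  NumericMatrix out(H * W, 9 * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *ch = px + (size_t)c * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        double *col = po + (size_t)(c * 9 + (dx + 1) * 3 + (dy + 1)) * H * W;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx;
          double *dst = col + (size_t)j * H;
          if (sj < 0 || sj >= W) continue;  // stays zero
          const double *src = ch + (size_t)sj * H;
          int i0 = dy < 0 ? 1 : 0;
          int i1 = dy > 0 ? H - 1 : H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + dy];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3x3: scatter-accumulate a (H*W, 9*C) gradient back to an
// (H, W, C) input gradient.
// [[Rcpp::export(name = ".col2im3x3_cpp")]]
NumericVector col2im3x3_cpp(NumericMatrix dcol, int H, int W, int C) {
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  double *po = out.begin();
  const double *pd = dcol.begin();
  for (int c = 0; c < C; ++c) {
    double *ch = po + (size_t)c * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const double *col = pd + (size_t)(c * 9 + (dx + 1) * 3 + (dy + 1)) * H * W;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          const double *src = col + (size_t)j * H;
          double *dst = ch + (size_t)sj * H;
          int i0 = dy < 0 ? 1 : 0;
          int i1 = dy > 0 ? H - 1 : H;
          for (int i = i0; i < i1; ++i) dst[i + dy] += src[i];
        }
      }
    }
  }
  return out;
}

// In-plane rigid resampling (rotation about the slice centre plus a
// row/column shift) with bilinear interpolation; out-of-bounds source
// coordinates yield 0. Rotation angle is in degrees, positive =
// counter-clockwise in (row, col) coordinates. When nearest = true the
// nearest-neighbour value is taken instead (used for binary masks).
// [[Rcpp::export(name = ".rigid_warp_cpp")]]
NumericMatrix rigid_warp_cpp(NumericMatrix x, double angle_deg,
                             double shift_r, double shift_c,
                             bool nearest = false) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cr = (nr + 1) / 2.0, cc = (nc + 1) / 2.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      // inverse map: undo shift, then rotate by -angle about centre
      double r = (i + 1) - shift_r - cr;
      double c = (j + 1) - shift_c - cc;
      double sr = ct * r + st * c + cr;
      double sc = -st * r + ct * c + cc;
      if (nearest) {
        int ri = (int)std::lround(sr) - 1, ci = (int)std::lround(sc) - 1;
        if (ri >= 0 && ri < nr && ci >= 0 && ci < nc) out(i, j) = x(ri, ci);
      } else {
        double fr = sr - 1.0, fc = sc - 1.0;
        int r0 = (int)std::floor(fr), c0 = (int)std::floor(fc);
        double wr = fr - r0, wc = fc - c0;
        double v = 0.0;
        for (int a = 0; a <= 1; ++a) {
          for (int b = 0; b <= 1; ++b) {
            int rr = r0 + a, cc2 = c0 + b;
            if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
            double wgt = (a ? wr : 1.0 - wr) * (b ? wc : 1.0 - wc);
            v += wgt * x(rr, cc2);
          }
        }
        out(i, j) = v;
      }
    }
  }
  return out;
}
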