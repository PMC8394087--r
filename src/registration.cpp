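#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inverse-mapped bilinear resampling of a rigid transform.
// Convention (shared with the R layer): (x, y) = (column, row), origin
// top-left, rotation counter-clockwise by `angle` degrees about the frame
// centre ((W-1)/2, (H-1)/2), followed by translation (tx, ty) in pixels.
// Out-of-frame samples are filled with 0.
// [[Rcpp::export(name = "cpp_apply_rigid")]]
NumericMatrix cpp_apply_rigid(const NumericMatrix& img, double angle,
                              double tx, double ty) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      // invert: rotate by -angle after removing translation and centre
      const double dx = c - cx - tx;
      const double dy = r - cy - ty;
      const double sx = ct * dx + st * dy + cx;
      const double sy = -st * dx + ct * dy + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      if (x0 < -1 || x0 > W - 1 || y0 < -1 || y0 > H - 1) continue;
      const double fx = sx - x0, fy = sy - y0;
      double v = 0.0;
      const bool x0ok = x0 >= 0 && x0 < W, x1ok = x0 + 1 >= 0 && x0 + 1 < W;
      const bool y0ok = y0 >= 0 && y0 < H, y1ok = y0 + 1 >= 0 && y0 + 1 < H;
      if (y0ok && x0ok) v += (1 - fy) * (1 - fx) * img(y0, x0);
      if (y0ok && x1ok) v += (1 - fy) * fx * img(y0, x0 + 1);
      if (y1ok && x0ok) v += fy * (1 - fx) * img(y0 + 1, x0);
      if (y1ok && x1ok) v += fy * fx * img(y0 + 1, x0 + 1);
      out(r, c) = v;
    }
  }
  return out;
}

static double mi_from_joint(const std::vector<double>& joint, int nbins,
                            double total) {
  std::vector<double> pr(nbins, 0.0), pf(nbins, 0.0);
  for (int f = 0; f < nbins; ++f)
    for (int r = 0; r < nbins; ++r) {
      pf[f] += joint[f * nbins + r];
      pr[r] += joint[f * nbins + r];
    }
  double mi = 0.0;
  for (int f = 0; f < nbins; ++f)
    for (int r = 0; r < nbins; ++r) {
      const double p = joint[f * nbins + r] / total;
      if (p > 0.0)
        mi += p * std::log(p / ((pf[f] / total) * (pr[r] / total)));
    }
  return mi;
}

static inline int bin_of(double v, double lo, double w, int nbins) {
  int b = (int)std::floor((v - lo) / w);
  if (b < 0) b = 0;
  if (b >= nbins) b = nbins - 1;
  return b;
}

// Mutual information of two equally sized images from an nbins x nbins joint
// intensity histogram over [lo, hi]; natural logarithm, 0*log(0) = 0.
// [[Rcpp::export(name = "cpp_mutual_information")]]
double cpp_mutual_information(const NumericMatrix& a, const NumericMatrix& b,
                              int nbins, double lo, double hi) {
  const R_xlen_t n = a.size();
  const double w = (hi > lo) ? (hi - lo) / nbins : 1.0;
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  for (R_xlen_t i = 0; i < n; ++i)
    joint[bin_of(a[i], lo, w, nbins) * nbins + bin_of(b[i], lo, w, nbins)] += 1.0;
  return mi_from_joint(joint, nbins, (double)n);
}

// MI objective of a candidate rigid transform: resample the floating image
// and histogram against the reference in one pass (no intermediate copy).
// [[Rcpp::export(name = "cpp_rigid_mi")]]
double cpp_rigid_mi(const NumericMatrix& floating, const NumericMatrix& reference,
                    double angle, double tx, double ty, int nbins,
                    double lo, double hi) {
  const int H = floating.nrow(), W = floating.ncol();
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double w = (hi > lo) ? (hi - lo) / nbins : 1.0;
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const double dx = c - cx - tx;
      const double dy = r - cy - ty;
      const double sx = ct * dx + st * dy + cx;
      const double sy = -st * dx + ct * dy + cy;
      double v = 0.0;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      if (x0 >= -1 && x0 <= W - 1 && y0 >= -1 && y0 <= H - 1) {
        const double fx = sx - x0, fy = sy - y0;
        const bool x0ok = x0 >= 0 && x0 < W, x1ok = x0 + 1 < W && x0 + 1 >= 0;
        const bool y0ok = y0 >= 0 && y0 < H, y1ok = y0 + 1 < H && y0 + 1 >= 0;
        if (y0ok && x0ok) v += (1 - fy) * (1 - fx) * floating(y0, x0);
        if (y0ok && x1ok) v += (1 - fy) * fx * floating(y0, x0 + 1);
        if (y1ok && x0ok) v += fy * (1 - fx) * floating(y0 + 1, x0);
        if (y1ok && x1ok) v += fy * fx * floating(y0 + 1, x0 + 1);
      }
      joint[bin_of(v, lo, w, nbins) * nbins + bin_of(reference(r, c), lo, w, nbins)] += 1.0;
    }
  }
  return mi_from_joint(joint, nbins, (double)(H * W));
}
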