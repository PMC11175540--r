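// Low-level kernels: Kaiser-Bessel gridding (NUFFT spread/interpolate),
// linear-interpolation warping with its exact transpose, and a separable
// convolution used for Gaussian field regularization.
//
// Conventions shared with the R layer:
//  - sample coordinates arrive as 0-based fractional positions on the
//    (oversampled) grid; out-of-range positions wrap periodically, which is
//    the correct semantics for a DFT spectrum;
//  - warp displacements are in voxel units, pull-back convention
//    out(r) = img(r + u(r)), with nearest-edge clamping outside the grid;
//  - complex arrays are R complex vectors with a dim attribute.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double kb_weight(double u, double halfw, double beta,
                               double i0beta) {
  double t = 1.0 - (u / halfw) * (u / halfw);
  if (t <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(t), 0.0, 1.0) / i0beta;
}

// Per-sample kernel support: indices and weights along each axis.
struct AxisSupport {
  int idx[3][16];
  double w[3][16];
};

static void axis_support(const double *pos, int d, const int *dims, int width,
                         double beta, double i0beta, AxisSupport &sup) {
  double halfw = width / 2.0;
  for (int a = 0; a < d; ++a) {
    int j0 = (int)std::ceil(pos[a] - halfw);
    int M = dims[a];
    for (int t = 0; t < width; ++t) {
      int j = j0 + t;
      sup.w[a][t] = kb_weight(j - pos[a], halfw, beta, i0beta);
      int jj = j % M;
      if (jj < 0) jj += M;
      sup.idx[a][t] = jj;
    }
  }
}

// Precompute per-sample kernel support tables (flat indices restricted to
// per-axis index/weight pairs) so repeated applications skip all kernel
// evaluations. Returns idx [n, width*d] (0-based, wrapped) and w
// [n, width*d], axis-major blocks.
// [[Rcpp::export(name = ".kb_tables")]]
List kb_tables_cpp(NumericMatrix pos, IntegerVector dims, int width,
                   double beta) {
  int n = pos.nrow(), d = pos.ncol();
  if (d < 1 || d > 3) stop("only 1-3 dimensions supported");
  if (width > 16) stop("kernel width > 16 not supported");
  int dm[3] = {1, 1, 1};
  for (int a = 0; a < d; ++a) dm[a] = dims[a];
  double i0beta = R::bessel_i(beta, 0.0, 1.0);
  IntegerMatrix idx(n, width * d);
  NumericMatrix wt(n, width * d);
  AxisSupport sup;
  double p[3];
  for (int s = 0; s < n; ++s) {
    for (int a = 0; a < d; ++a) p[a] = pos(s, a);
    axis_support(p, d, dm, width, beta, i0beta, sup);
    for (int a = 0; a < d; ++a)
      for (int t = 0; t < width; ++t) {
        idx(s, a * width + t) = sup.idx[a][t];
        wt(s, a * width + t) = sup.w[a][t];
      }
  }
  return List::create(Named("idx") = idx, Named("w") = wt);
}

// [[Rcpp::export(name = ".kb_interp_pre")]]
ComplexVector kb_interp_pre_cpp(IntegerMatrix idx, NumericMatrix wt,
                                ComplexVector grid, IntegerVector dims,
                                int width) {
  int n = idx.nrow();
  int d = idx.ncol() / width;
  int dm[3] = {1, 1, 1};
  for (int a = 0; a < d; ++a) dm[a] = dims[a];
  ComplexVector out(n);
  for (int s = 0; s < n; ++s) {
    double accre = 0.0, accim = 0.0;
    int tz_max = (d >= 3) ? width : 1;
    int ty_max = (d >= 2) ? width : 1;
    for (int tz = 0; tz < tz_max; ++tz) {
      double wz = (d >= 3) ? wt(s, 2 * width + tz) : 1.0;
      int oz = (d >= 3) ? idx(s, 2 * width + tz) * dm[0] * dm[1] : 0;
      for (int ty = 0; ty < ty_max; ++ty) {
        double wyz = wz * ((d >= 2) ? wt(s, width + ty) : 1.0);
        int oyz = oz + ((d >= 2) ? idx(s, width + ty) * dm[0] : 0);
        for (int tx = 0; tx < width; ++tx) {
          double w = wyz * wt(s, tx);
          int off = oyz + idx(s, tx);
          accre += w * grid[off].r;
          accim += w * grid[off].i;
        }
      }
    }
    out[s].r = accre;
    out[s].i = accim;
  }
  return out;
}

// [[Rcpp::export(name = ".kb_spread_pre")]]
ComplexVector kb_spread_pre_cpp(IntegerMatrix idx, NumericMatrix wt,
                                ComplexVector vals, IntegerVector dims,
                                int width) {
  int n = idx.nrow();
  int d = idx.ncol() / width;
  int dm[3] = {1, 1, 1};
  long total = 1;
  for (int a = 0; a < d; ++a) { dm[a] = dims[a]; total *= dims[a]; }
  ComplexVector out(total);
  for (long i = 0; i < total; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
  for (int s = 0; s < n; ++s) {
    double vr = vals[s].r, vi = vals[s].i;
    int tz_max = (d >= 3) ? width : 1;
    int ty_max = (d >= 2) ? width : 1;
    for (int tz = 0; tz < tz_max; ++tz) {
      double wz = (d >= 3) ? wt(s, 2 * width + tz) : 1.0;
      int oz = (d >= 3) ? idx(s, 2 * width + tz) * dm[0] * dm[1] : 0;
      for (int ty = 0; ty < ty_max; ++ty) {
        double wyz = wz * ((d >= 2) ? wt(s, width + ty) : 1.0);
        int oyz = oz + ((d >= 2) ? idx(s, width + ty) * dm[0] : 0);
        for (int tx = 0; tx < width; ++tx) {
          double w = wyz * wt(s, tx);
          int off = oyz + idx(s, tx);
          out[off].r += w * vr;
          out[off].i += w * vi;
        }
      }
    }
  }
  return out;
}

// Corner enumeration shared by warp pull/push: for voxel index v (flattened)
// with source position p, accumulate the 2^d corner indices and weights.
struct Corners {
  int idx[8];
  double w[8];
  int n;
};

static void corner_weights(const double *p, int d, const int *dm,
                           Corners &c) {
  int lo[3];
  double fr[3];
  for (int a = 0; a < d; ++a) {
    double x = p[a];
    if (x < 0.0) x = 0.0;
    double xmax = dm[a] - 1.0;
    if (x > xmax) x = xmax;
    int l = (int)std::floor(x);
    if (l > dm[a] - 2) l = dm[a] - 2;
    if (l < 0) l = 0;
    lo[a] = l;
    fr[a] = x - l;
  }
  c.n = 1 << d;
  for (int m = 0; m < c.n; ++m) {
    double w = 1.0;
    long off = 0, mult = 1;
    for (int a = 0; a < d; ++a) {
      int hi = (m >> a) & 1;
      w *= hi ? fr[a] : (1.0 - fr[a]);
      off += (lo[a] + hi) * mult;
      mult *= dm[a];
    }
    c.idx[m] = (int)off;
    c.w[m] = w;
  }
}

// [[Rcpp::export(name = ".warp_pull")]]
ComplexVector warp_pull_cpp(ComplexVector img, List disp, IntegerVector dims) {
  int d = dims.size();
  if (d < 2 || d > 3) stop("only 2-3 dimensions supported");
  int dm[3] = {1, 1, 1};
  long total = 1;
  for (int a = 0; a < d; ++a) { dm[a] = dims[a]; total *= dims[a]; }
  std::vector<NumericVector> u;
  for (int a = 0; a < d; ++a) u.push_back(as<NumericVector>(disp[a]));
  ComplexVector out(total);
  Corners c;
  double p[3];
  int iv[3] = {0, 0, 0};
  for (long v = 0; v < total; ++v) {
    for (int a = 0; a < d; ++a) p[a] = iv[a] + u[a][v];
    corner_weights(p, d, dm, c);
    double accre = 0.0, accim = 0.0;
    for (int m = 0; m < c.n; ++m) {
      accre += c.w[m] * img[c.idx[m]].r;
      accim += c.w[m] * img[c.idx[m]].i;
    }
    out[v].r = accre;
    out[v].i = accim;
    ++iv[0];
    for (int a = 0; a < d - 1 && iv[a] == dm[a]; ++a) { iv[a] = 0; ++iv[a + 1]; }
  }
  return out;
}

// [[Rcpp::export(name = ".warp_push")]]
ComplexVector warp_push_cpp(ComplexVector y, List disp, IntegerVector dims) {
  int d = dims.size();
  if (d < 2 || d > 3) stop("only 2-3 dimensions supported");
  int dm[3] = {1, 1, 1};
  long total = 1;
  for (int a = 0; a < d; ++a) { dm[a] = dims[a]; total *= dims[a]; }
  std::vector<NumericVector> u;
  for (int a = 0; a < d; ++a) u.push_back(as<NumericVector>(disp[a]));
  ComplexVector out(total);
  for (long i = 0; i < total; ++i) { out[i].r = 0.0; out[i].i = 0.0; }
  Corners c;
  double p[3];
  int iv[3] = {0, 0, 0};
  for (long v = 0; v < total; ++v) {
    for (int a = 0; a < d; ++a) p[a] = iv[a] + u[a][v];
    corner_weights(p, d, dm, c);
    for (int m = 0; m < c.n; ++m) {
      out[c.idx[m]].r += c.w[m] * y[v].r;
      out[c.idx[m]].i += c.w[m] * y[v].i;
    }
    ++iv[0];
    for (int a = 0; a < d - 1 && iv[a] == dm[a]; ++a) { iv[a] = 0; ++iv[a + 1]; }
  }
  return out;
}

// Separable convolution along one axis with replicate-edge padding.
// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dims, int axis,
                            NumericVector kernel) {
  int d = dims.size();
  if (axis < 0 || axis >= d) stop("bad axis");
  int r = (kernel.size() - 1) / 2;
  long total = 1;
  for (int a = 0; a < d; ++a) total *= dims[a];
  long stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  int n = dims[axis];
  NumericVector out(total);
  long outer = total / n;
  for (long o = 0; o < outer; ++o) {
    // Base index of this line: decompose o into (inner, rest).
    long inner = o % stride;
    long rest = o / stride;
    long base = inner + rest * stride * n;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int j = i + t;
        if (j < 0) j = 0;
        if (j >= n) j = n - 1;
        acc += kernel[t + r] * arr[base + (long)j * stride];
      }
      out[base + (long)i * stride] = acc;
    }
  }
  return out;
}
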