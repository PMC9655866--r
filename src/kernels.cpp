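// Numerical kernels: 3D convolution (vol2col + GEMM) with gradients,
// trilinear/nearest resampling, average pooling, a separable squared
// Euclidean distance transform, and the gamma-index neighbourhood search.
//
// Array layout convention (column-major, as passed from R):
//   feature tensors  : dim = (d1, d2, d3, C, N)
//   volumes          : dim = (d1, d2, d3)
// Convolution weights: matrix K x Cout with K = Cin * k^3, the K index
// running fastest over kernel offset a3, then a2, a1, then input channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

// Build the vol2col matrix for a slab of output z-planes [z0, z1).
// Rows = output voxels of the slab, cols = K. Memory for the col matrix is
// bounded by tiling over z so that full-width 128^3 layers stay in budget.
static void vol2col_slab(const double* x, int d1, int d2, int d3, int cin,
                         int k, int s, int p, int z0, int z1, arma::mat& col) {
  const int o1 = out_extent(d1, k, s, p);
  const int o2 = out_extent(d2, k, s, p);
  const int oz = z1 - z0;
  const long n_out = (long)o1 * o2 * oz;
  col.set_size(n_out, (long)cin * k * k * k);
  col.zeros();
  // valid output index range for kernel offset a: 0 <= j*s - p + a < d
  auto lo = [&](int a) { return std::max(0, (p - a + s - 1) / s); };
  auto hi = [&](int a, int d, int o) {
    return std::min(o, (d + p - a + s - 1) / s);
  };
  long t = 0;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (long)c * d1 * d2 * d3;
    for (int a1 = 0; a1 < k; ++a1)
      for (int a2 = 0; a2 < k; ++a2)
        for (int a3 = 0; a3 < k; ++a3, ++t) {
          double* dst = col.colptr(t);
          const int j1lo = lo(a1), j1hi = hi(a1, d1, o1);
          const int j2lo = lo(a2), j2hi = hi(a2, d2, o2);
          const int j3lo = std::max(z0, lo(a3)), j3hi = std::min(z1, hi(a3, d3, out_extent(d3, k, s, p)));
          if (j1hi <= j1lo) continue;
          for (int j3 = j3lo; j3 < j3hi; ++j3) {
            const int i3 = j3 * s - p + a3;
            for (int j2 = j2lo; j2 < j2hi; ++j2) {
              const int i2 = j2 * s - p + a2;
              double* drow = dst + (long)o1 * (j2 + (long)o2 * (j3 - z0));
              const double* srow = xc + (long)d1 * (i2 + (long)d2 * i3);
              if (s == 1) {
                const int off = a1 - p;
                std::copy(srow + j1lo + off, srow + j1hi + off, drow + j1lo);
              } else {
                int i1 = j1lo * s - p + a1;
                for (int j1 = j1lo; j1 < j1hi; ++j1, i1 += s)
                  drow[j1] = srow[i1];
              }
            }
          }
        }
  }
}


// Scatter-add of a slab col matrix back onto the input volume.
static void col2vol_slab(const arma::mat& col, double* gx, int d1, int d2,
                         int d3, int cin, int k, int s, int p, int z0, int z1) {
  const int o1 = out_extent(d1, k, s, p);
  const int o2 = out_extent(d2, k, s, p);
  const int o3 = out_extent(d3, k, s, p);
  auto lo = [&](int a) { return std::max(0, (p - a + s - 1) / s); };
  auto hi = [&](int a, int d, int o) {
    return std::min(o, (d + p - a + s - 1) / s);
  };
  long t = 0;
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + (long)c * d1 * d2 * d3;
    for (int a1 = 0; a1 < k; ++a1)
      for (int a2 = 0; a2 < k; ++a2)
        for (int a3 = 0; a3 < k; ++a3, ++t) {
          const double* src = col.colptr(t);
          const int j1lo = lo(a1), j1hi = hi(a1, d1, o1);
          const int j2lo = lo(a2), j2hi = hi(a2, d2, o2);
          const int j3lo = std::max(z0, lo(a3));
          const int j3hi = std::min(z1, hi(a3, d3, o3));
          if (j1hi <= j1lo) continue;
          for (int j3 = j3lo; j3 < j3hi; ++j3) {
            const int i3 = j3 * s - p + a3;
            for (int j2 = j2lo; j2 < j2hi; ++j2) {
              const int i2 = j2 * s - p + a2;
              const double* srow = src + (long)o1 * (j2 + (long)o2 * (j3 - z0));
              double* drow = gc + (long)d1 * (i2 + (long)d2 * i3);
              if (s == 1) {
                const int off = a1 - p;
                for (int j1 = j1lo; j1 < j1hi; ++j1) drow[j1 + off] += srow[j1];
              } else {
                int i1 = j1lo * s - p + a1;
                for (int j1 = j1lo; j1 < j1hi; ++j1, i1 += s)
                  drow[i1] += srow[j1];
              }
            }
          }
        }
  }
}

// Tile thickness keeping each col matrix under ~128 MB.
static int slab_thickness(int o1, int o2, long K) {
  double bytes_per_plane = (double)o1 * o2 * K * 8.0;
  int t = (int)std::floor(134217728.0 / bytes_per_plane);
  return std::max(1, t);
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                             int k, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2], cin = dm[3], n = dm[4];
  int cout = W.ncol();
  int o1 = out_extent(d1, k, stride, pad);
  int o2 = out_extent(d2, k, stride, pad);
  int o3 = out_extent(d3, k, stride, pad);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("input smaller than one kernel support");
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  NumericVector y((long)o1 * o2 * o3 * cout * n);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, cout, n);
  arma::mat col;
  const long samp_in = (long)d1 * d2 * d3 * cin;
  const long samp_out = (long)o1 * o2 * o3 * cout;
  const long plane = (long)o1 * o2;
  const int thick = slab_thickness(o1, o2, W.nrow());
  for (int s = 0; s < n; ++s) {
    for (int z0 = 0; z0 < o3; z0 += thick) {
      int z1 = std::min(z0 + thick, o3);
      vol2col_slab(x.begin() + s * samp_in, d1, d2, d3, cin, k, stride, pad,
                   z0, z1, col);
      arma::mat out = col * Wm;                     // slab_out x cout
      for (int c = 0; c < cout; ++c) out.col(c) += b[c];
      // slab rows are contiguous within each output channel
      const long slab = plane * (z1 - z0);
      for (int c = 0; c < cout; ++c)
        std::copy(out.colptr(c), out.colptr(c) + slab,
                  y.begin() + s * samp_out + (long)c * o1 * o2 * o3 + plane * z0);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix W, NumericVector gy,
                    int k, int stride, int pad, bool need_gx) {
  IntegerVector dm = x.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2], cin = dm[3], n = dm[4];
  IntegerVector dmo = gy.attr("dim");
  int o1 = dmo[0], o2 = dmo[1], o3 = dmo[2], cout = dmo[3];
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat gW(W.nrow(), W.ncol(), arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = dm;
  }
  arma::mat col;
  const long samp_in = (long)d1 * d2 * d3 * cin;
  const long samp_out = (long)o1 * o2 * o3 * cout;
  const long plane = (long)o1 * o2;
  const int thick = slab_thickness(o1, o2, W.nrow());
  for (int s = 0; s < n; ++s) {
    for (int z0 = 0; z0 < o3; z0 += thick) {
      int z1 = std::min(z0 + thick, o3);
      const long slab = plane * (z1 - z0);
      arma::mat gym(slab, cout);
      for (int c = 0; c < cout; ++c)
        std::copy(gy.begin() + s * samp_out + (long)c * o1 * o2 * o3 + plane * z0,
                  gy.begin() + s * samp_out + (long)c * o1 * o2 * o3 + plane * z0 + slab,
                  gym.colptr(c));
      vol2col_slab(x.begin() + s * samp_in, d1, d2, d3, cin, k, stride, pad,
                   z0, z1, col);
      gW += col.t() * gym;
      gb += arma::sum(gym, 0).t();
      if (need_gx) {
        arma::mat gcol = gym * Wm.t();             // slab_out x K
        col2vol_slab(gcol, gx.begin() + s * samp_in, d1, d2, d3, cin, k,
                     stride, pad, z0, z1);
      }
    }
  }
  List res = List::create(_["gW"] = wrap(gW), _["gb"] = wrap(gb));
  if (need_gx) res["gx"] = gx;
  return res;
}

// Half-pixel coordinate mapping: src = (i + 0.5) * (in/out) - 0.5.
// mode 0 = trilinear, 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector out_dim, int mode) {
  IntegerVector dm = x.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int C = 1, N = 1;
  if (dm.size() == 5) { C = dm[3]; N = dm[4]; }
  int o1 = out_dim[0], o2 = out_dim[1], o3 = out_dim[2];
  double r1 = (double)d1 / o1, r2 = (double)d2 / o2, r3 = (double)d3 / o3;
  NumericVector y((long)o1 * o2 * o3 * C * N);
  if (dm.size() == 5)
    y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  else
    y.attr("dim") = IntegerVector::create(o1, o2, o3);
  std::vector<int> lo1(o1), lo2(o2), lo3(o3);
  std::vector<double> w1(o1), w2(o2), w3(o3);
  auto prep = [&](int o, double r, int d, std::vector<int>& lo, std::vector<double>& w) {
    for (int i = 0; i < o; ++i) {
      double s = (i + 0.5) * r - 0.5;
      if (mode == 1) {
        int ni = (int)std::floor(s + 0.5);
        lo[i] = std::min(std::max(ni, 0), d - 1); w[i] = 0.0;
      } else {
        double fs = std::floor(s);
        int l = (int)fs;
        double f = s - fs;
        if (l < 0) { l = 0; f = 0.0; }
        if (l >= d - 1) { l = d - 1; f = 0.0; }
        lo[i] = l; w[i] = f;
      }
    }
  };
  prep(o1, r1, d1, lo1, w1); prep(o2, r2, d2, lo2, w2); prep(o3, r3, d3, lo3, w3);
  const long ch_in = (long)d1 * d2 * d3, ch_out = (long)o1 * o2 * o3;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + cn * ch_in;
    double* yc = y.begin() + cn * ch_out;
    for (int j3 = 0; j3 < o3; ++j3)
      for (int j2 = 0; j2 < o2; ++j2)
        for (int j1 = 0; j1 < o1; ++j1) {
          double v;
          if (mode == 1) {
            v = xc[(long)lo1[j1] + (long)d1 * (lo2[j2] + (long)d2 * lo3[j3])];
          } else {
            int l1 = lo1[j1], l2 = lo2[j2], l3 = lo3[j3];
            int h1 = std::min(l1 + 1, d1 - 1), h2 = std::min(l2 + 1, d2 - 1),
                h3 = std::min(l3 + 1, d3 - 1);
            double f1 = w1[j1], f2 = w2[j2], f3 = w3[j3];
            auto at = [&](int i1, int i2, int i3) {
              return xc[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)];
            };
            v = (1-f1)*(1-f2)*(1-f3)*at(l1,l2,l3) + f1*(1-f2)*(1-f3)*at(h1,l2,l3)
              + (1-f1)*f2*(1-f3)*at(l1,h2,l3)     + f1*f2*(1-f3)*at(h1,h2,l3)
              + (1-f1)*(1-f2)*f3*at(l1,l2,h3)     + f1*(1-f2)*f3*at(h1,l2,h3)
              + (1-f1)*f2*f3*at(l1,h2,h3)         + f1*f2*f3*at(h1,h2,h3);
          }
          yc[(long)j1 + (long)o1 * (j2 + (long)o2 * j3)] = v;
        }
  }
  return y;
}

// Adjoint of trilinear cpp_resize3d (for upsampling gradients).
// [[Rcpp::export]]
NumericVector cpp_resize3d_bwd(NumericVector gy, IntegerVector in_dim) {
  IntegerVector dmo = gy.attr("dim");
  int o1 = dmo[0], o2 = dmo[1], o3 = dmo[2];
  int C = 1, N = 1;
  if (dmo.size() == 5) { C = dmo[3]; N = dmo[4]; }
  int d1 = in_dim[0], d2 = in_dim[1], d3 = in_dim[2];
  double r1 = (double)d1 / o1, r2 = (double)d2 / o2, r3 = (double)d3 / o3;
  NumericVector gx((long)d1 * d2 * d3 * C * N);
  if (dmo.size() == 5)
    gx.attr("dim") = IntegerVector::create(d1, d2, d3, C, N);
  else
    gx.attr("dim") = IntegerVector::create(d1, d2, d3);
  std::vector<int> lo1(o1), lo2(o2), lo3(o3);
  std::vector<double> w1(o1), w2(o2), w3(o3);
  auto prep = [&](int o, double r, int d, std::vector<int>& lo, std::vector<double>& w) {
    for (int i = 0; i < o; ++i) {
      double s = (i + 0.5) * r - 0.5;
      double fs = std::floor(s);
      int l = (int)fs; double f = s - fs;
      if (l < 0) { l = 0; f = 0.0; }
      if (l >= d - 1) { l = d - 1; f = 0.0; }
      lo[i] = l; w[i] = f;
    }
  };
  prep(o1, r1, d1, lo1, w1); prep(o2, r2, d2, lo2, w2); prep(o3, r3, d3, lo3, w3);
  const long ch_in = (long)d1 * d2 * d3, ch_out = (long)o1 * o2 * o3;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    double* gc = gx.begin() + cn * ch_in;
    const double* gyc = gy.begin() + cn * ch_out;
    for (int j3 = 0; j3 < o3; ++j3)
      for (int j2 = 0; j2 < o2; ++j2)
        for (int j1 = 0; j1 < o1; ++j1) {
          double g = gyc[(long)j1 + (long)o1 * (j2 + (long)o2 * j3)];
          if (g == 0.0) continue;
          int l1 = lo1[j1], l2 = lo2[j2], l3 = lo3[j3];
          int h1 = std::min(l1 + 1, d1 - 1), h2 = std::min(l2 + 1, d2 - 1),
              h3 = std::min(l3 + 1, d3 - 1);
          double f1 = w1[j1], f2 = w2[j2], f3 = w3[j3];
          auto add = [&](int i1, int i2, int i3, double w) {
            gc[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)] += w * g;
          };
          add(l1,l2,l3,(1-f1)*(1-f2)*(1-f3)); add(h1,l2,l3,f1*(1-f2)*(1-f3));
          add(l1,h2,l3,(1-f1)*f2*(1-f3));     add(h1,h2,l3,f1*f2*(1-f3));
          add(l1,l2,h3,(1-f1)*(1-f2)*f3);     add(h1,l2,h3,f1*(1-f2)*f3);
          add(l1,h2,h3,(1-f1)*f2*f3);         add(h1,h2,h3,f1*f2*f3);
        }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_fwd(NumericVector x, int f) {
  IntegerVector dm = x.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2], C = dm[3], N = dm[4];
  int o1 = d1 / f, o2 = d2 / f, o3 = d3 / f;
  NumericVector y((long)o1 * o2 * o3 * C * N);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  const double inv = 1.0 / ((double)f * f * f);
  const long ch_in = (long)d1 * d2 * d3, ch_out = (long)o1 * o2 * o3;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + cn * ch_in;
    double* yc = y.begin() + cn * ch_out;
    for (int j3 = 0; j3 < o3; ++j3)
      for (int j2 = 0; j2 < o2; ++j2)
        for (int j1 = 0; j1 < o1; ++j1) {
          double acc = 0.0;
          for (int a3 = 0; a3 < f; ++a3)
            for (int a2 = 0; a2 < f; ++a2)
              for (int a1 = 0; a1 < f; ++a1)
                acc += xc[(long)(j1*f+a1) + (long)d1 * ((j2*f+a2) + (long)d2 * (j3*f+a3))];
          yc[(long)j1 + (long)o1 * (j2 + (long)o2 * j3)] = acc * inv;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_bwd(NumericVector gy, IntegerVector in_dim, int f) {
  IntegerVector dmo = gy.attr("dim");
  int o1 = dmo[0], o2 = dmo[1], o3 = dmo[2], C = dmo[3], N = dmo[4];
  int d1 = in_dim[0], d2 = in_dim[1], d3 = in_dim[2];
  NumericVector gx((long)d1 * d2 * d3 * C * N);
  gx.attr("dim") = IntegerVector::create(d1, d2, d3, C, N);
  const double inv = 1.0 / ((double)f * f * f);
  const long ch_in = (long)d1 * d2 * d3, ch_out = (long)o1 * o2 * o3;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    double* gc = gx.begin() + cn * ch_in;
    const double* gyc = gy.begin() + cn * ch_out;
    for (int j3 = 0; j3 < o3; ++j3)
      for (int j2 = 0; j2 < o2; ++j2)
        for (int j1 = 0; j1 < o1; ++j1) {
          double g = gyc[(long)j1 + (long)o1 * (j2 + (long)o2 * j3)] * inv;
          for (int a3 = 0; a3 < f; ++a3)
            for (int a2 = 0; a2 < f; ++a2)
              for (int a1 = 0; a1 < f; ++a1)
                gc[(long)(j1*f+a1) + (long)d1 * ((j2*f+a2) + (long)d2 * (j3*f+a3))] += g;
        }
  }
  return gx;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform with sample
// spacing h; applied separably along the three axes.
static void dt1d(std::vector<double>& fvals, double h) {
  const int n = (int)fvals.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((fvals[q] + (double)q*q*h*h) - (fvals[p] + (double)p*p*h*h)) /
          (2.0 * h * h * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk; v[kk] = q; z[kk] = s; z[kk + 1] = INFINITY;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q] = (double)(q - p) * (q - p) * h * h + fvals[p];
  }
  fvals = d;
}

// Euclidean distance (mm) from each voxel to the nearest TRUE voxel of mask.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const double BIG = 1e30;
  std::vector<double> f((long)d1 * d2 * d3);
  for (long i = 0; i < (long)d1 * d2 * d3; ++i) f[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> line;
  // axis 1
  line.resize(d1);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2) {
      long base = (long)d1 * (i2 + (long)d2 * i3);
      for (int i1 = 0; i1 < d1; ++i1) line[i1] = f[base + i1];
      dt1d(line, spacing[0]);
      for (int i1 = 0; i1 < d1; ++i1) f[base + i1] = line[i1];
    }
  // axis 2
  line.resize(d2);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i1 = 0; i1 < d1; ++i1) {
      for (int i2 = 0; i2 < d2; ++i2) line[i2] = f[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)];
      dt1d(line, spacing[1]);
      for (int i2 = 0; i2 < d2; ++i2) f[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)] = line[i2];
    }
  // axis 3
  line.resize(d3);
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      for (int i3 = 0; i3 < d3; ++i3) line[i3] = f[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)];
      dt1d(line, spacing[2]);
      for (int i3 = 0; i3 < d3; ++i3) f[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)] = line[i3];
    }
  NumericVector out((long)d1 * d2 * d3);
  out.attr("dim") = dm;
  for (long i = 0; i < (long)d1 * d2 * d3; ++i) out[i] = std::sqrt(f[i]);
  return out;
}

// Gamma index: for each eligible reference voxel, minimise
// sqrt(dose_term^2 + dist_term^2) over spatial offsets up to search_mm,
// with the evaluated dose trilinearly interpolated at mm resolution step_mm.
// Offsets are visited in order of increasing radius so the search stops as
// soon as the distance term alone exceeds the current best gamma.
// [[Rcpp::export]]
NumericVector cpp_gamma3d(NumericVector ref, NumericVector ev,
                          LogicalVector eligible, NumericVector spacing,
                          double dd_abs, double dta_mm, double step_mm,
                          double search_mm) {
  IntegerVector dm = ref.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  double sp1 = spacing[0], sp2 = spacing[1], sp3 = spacing[2];
  // precompute offsets sorted by radius
  int m1 = (int)std::floor(search_mm / step_mm);
  std::vector<std::array<double,4>> offs;  // r, x1mm, x2mm, x3mm
  offs.reserve((size_t)(2*m1+1) * (2*m1+1));
  for (int a1 = -m1; a1 <= m1; ++a1)
    for (int a2 = -m1; a2 <= m1; ++a2)
      for (int a3 = -m1; a3 <= m1; ++a3) {
        double x1 = a1 * step_mm, x2 = a2 * step_mm, x3 = a3 * step_mm;
        double r = std::sqrt(x1*x1 + x2*x2 + x3*x3);
        if (r <= search_mm) offs.push_back({r, x1, x2, x3});
      }
  std::sort(offs.begin(), offs.end(),
            [](const std::array<double,4>& a, const std::array<double,4>& b) {
              return a[0] < b[0];
            });
  auto interp = [&](double c1, double c2, double c3, bool& ok) {
    if (c1 < 0 || c2 < 0 || c3 < 0 || c1 > d1 - 1 || c2 > d2 - 1 || c3 > d3 - 1) {
      ok = false; return 0.0;
    }
    ok = true;
    int l1 = (int)std::floor(c1), l2 = (int)std::floor(c2), l3 = (int)std::floor(c3);
    int h1 = std::min(l1 + 1, d1 - 1), h2 = std::min(l2 + 1, d2 - 1), h3 = std::min(l3 + 1, d3 - 1);
    double f1 = c1 - l1, f2 = c2 - l2, f3 = c3 - l3;
    auto at = [&](int i1, int i2, int i3) {
      return ev[(long)i1 + (long)d1 * (i2 + (long)d2 * i3)];
    };
    return (1-f1)*(1-f2)*(1-f3)*at(l1,l2,l3) + f1*(1-f2)*(1-f3)*at(h1,l2,l3)
         + (1-f1)*f2*(1-f3)*at(l1,h2,l3)     + f1*f2*(1-f3)*at(h1,h2,l3)
         + (1-f1)*(1-f2)*f3*at(l1,l2,h3)     + f1*(1-f2)*f3*at(h1,l2,h3)
         + (1-f1)*f2*f3*at(l1,h2,h3)         + f1*f2*f3*at(h1,h2,h3);
  };
  NumericVector gam((long)d1 * d2 * d3, NA_REAL);
  gam.attr("dim") = dm;
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        long idx = (long)i1 + (long)d1 * (i2 + (long)d2 * i3);
        if (!eligible[idx]) continue;
        double rv = ref[idx];
        double best2 = INFINITY;
        for (const auto& o : offs) {
          double dist = o[0] / dta_mm;
          double dist2 = dist * dist;
          if (dist2 >= best2) break;
          bool ok;
          double evv = interp(i1 + o[1] / sp1, i2 + o[2] / sp2, i3 + o[3] / sp3, ok);
          if (!ok) continue;
          double dd = (evv - rv) / dd_abs;
          double g2 = dd * dd + dist2;
          if (g2 < best2) best2 = g2;
        }
        gam[idx] = std::sqrt(best2);
      }
  return gam;
}
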