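// Low-level array kernels for the 3D network and metrics.
// Layout convention (matches R column-major arrays):
//   feature maps are [d1, d2, d3, C, N]; spatial index is fastest.
//   conv weights are a matrix (k^3 * Cin) x Cout, i.e. the flattening of an
//   R array dim c(k, k, k, Cin, Cout).
//   transposed-conv (kernel 2, stride 2) weights are (8 * Cout) x Cin,
//   the flattening of dim c(2, 2, 2, Cout, Cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword spat_index(int x, int y, int z, int d1, int d2) {
  return (arma::uword)x + (arma::uword)d1 * ((arma::uword)y + (arma::uword)d2 * (arma::uword)z);
}

// Fill the im2col matrix: Nvox x (k^3*Cin) for one sample, same padding.
// Column r = (kx, ky, kz, ci); rows are output voxels (spatial-fastest), so
// every inner copy below is contiguous in both source and destination.
static void im2col_same(const double* x, int d1, int d2, int d3, int cin,
                        int k, arma::mat& col) {
  // NB: callers zero `col` once before the sample loop; the zero pattern
  // (out-of-bounds taps) is identical for every sample.
  const int pad = (k - 1) / 2;
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  const arma::uword k3 = (arma::uword)k * k * k;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (arma::uword)ci * nvox;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const arma::uword r = (arma::uword)kx + k * ((arma::uword)ky + k * (arma::uword)kz) + k3 * ci;
          double* cp = col.colptr(r);
          for (int z = 0; z < d3; ++z) {
            const int iz = z + kz - pad;
            if (iz < 0 || iz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int iy = y + ky - pad;
              if (iy < 0 || iy >= d2) continue;
              const int ix0 = kx - pad;
              const int xlo = std::max(0, -ix0);
              const int xhi = std::min(d1, d1 - ix0);
              const double* src = xc + spat_index(0, iy, iz, d1, d2) + ix0;
              double* dst = cp + spat_index(0, y, z, d1, d2);
              std::copy(src + xlo, src + xhi, dst + xlo);
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back into the input gradient (adjoint of im2col).
static void col2im_same(const arma::mat& col, int d1, int d2, int d3, int cin,
                        int k, double* dx) {
  const int pad = (k - 1) / 2;
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  const arma::uword k3 = (arma::uword)k * k * k;
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = dx + (arma::uword)ci * nvox;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const arma::uword r = (arma::uword)kx + k * ((arma::uword)ky + k * (arma::uword)kz) + k3 * ci;
          const double* cp = col.colptr(r);
          for (int z = 0; z < d3; ++z) {
            const int iz = z + kz - pad;
            if (iz < 0 || iz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int iy = y + ky - pad;
              if (iy < 0 || iy >= d2) continue;
              const int ix0 = kx - pad;
              const int xlo = std::max(0, -ix0);
              const int xhi = std::min(d1, d1 - ix0);
              double* dst = xc + spat_index(0, iy, iz, d1, d2) + ix0;
              const double* src = cp + spat_index(0, y, z, d1, d2);
              for (int xx = xlo; xx < xhi; ++xx) dst[xx] += src[xx];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector bias, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3], n = dims[4];
  const int cout = w.ncol();
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  NumericVector out(nvox * cout * (arma::uword)n);
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::vec b(bias.begin(), bias.size(), false);
  if (k == 1) {
    for (int i = 0; i < n; ++i) {
      arma::mat X(const_cast<double*>(x.begin()) + (arma::uword)i * nvox * cin,
                  nvox, cin, false);
      arma::mat Y(out.begin() + (arma::uword)i * nvox * cout, nvox, cout, false, true);
      Y = X * W;
      Y.each_row() += b.t();
    }
  } else {
    arma::mat col(nvox, (arma::uword)k * k * k * cin, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      im2col_same(x.begin() + (arma::uword)i * nvox * cin, d1, d2, d3, cin, k, col);
      arma::mat Y(out.begin() + (arma::uword)i * nvox * cout, nvox, cout, false, true);
      Y = col * W;
      Y.each_row() += b.t();
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                    NumericVector dy, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3], n = dims[4];
  const int cout = w.ncol();
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  NumericVector dx(x.size());
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dW(w.nrow(), w.ncol(), arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  if (k == 1) {
    for (int i = 0; i < n; ++i) {
      arma::mat X(const_cast<double*>(x.begin()) + (arma::uword)i * nvox * cin,
                  nvox, cin, false);
      arma::mat dY(const_cast<double*>(dy.begin()) + (arma::uword)i * nvox * cout,
                   nvox, cout, false);
      arma::mat dX(dx.begin() + (arma::uword)i * nvox * cin, nvox, cin, false, true);
      dX = dY * W.t();
      dW += X.t() * dY;
      db += arma::sum(dY, 0).t();
    }
  } else {
    arma::mat col(nvox, (arma::uword)k * k * k * cin, arma::fill::zeros);
    arma::mat dcol(nvox, (arma::uword)k * k * k * cin);
    for (int i = 0; i < n; ++i) {
      im2col_same(x.begin() + (arma::uword)i * nvox * cin, d1, d2, d3, cin, k, col);
      arma::mat dY(const_cast<double*>(dy.begin()) + (arma::uword)i * nvox * cout,
                   nvox, cout, false);
      dW += col.t() * dY;
      db += arma::sum(dY, 0).t();
      dcol = dY * W.t();
      col2im_same(dcol, d1, d2, d3, cin, k, dx.begin() + (arma::uword)i * nvox * cin);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector bias) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3], n = dims[4];
  const int cout = w.nrow() / 8;
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  const arma::uword onvox = (arma::uword)o1 * o2 * o3;
  NumericVector out(onvox * cout * (arma::uword)n);
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false); // (8*cout) x cin
  for (int i = 0; i < n; ++i) {
    arma::mat X(const_cast<double*>(x.begin()) + (arma::uword)i * nvox * cin,
                nvox, cin, false);
    arma::mat B = X * W.t(); // nvox x (8*cout), cols: (kx,ky,kz,co)
    double* o = out.begin() + (arma::uword)i * onvox * cout;
    for (int co = 0; co < cout; ++co) {
      const double bval = bias[co];
      double* oc = o + (arma::uword)co * onvox;
      for (int kz = 0; kz < 2; ++kz)
        for (int ky = 0; ky < 2; ++ky)
          for (int kx = 0; kx < 2; ++kx) {
            const arma::uword j = (arma::uword)(kx + 2 * ky + 4 * kz) + 8u * co;
            const double* src = B.colptr(j);
            for (int z = 0; z < d3; ++z)
              for (int y = 0; y < d2; ++y) {
                const arma::uword p = spat_index(0, y, z, d1, d2);
                double* dst = oc + spat_index(kx, 2 * y + ky, 2 * z + kz, o1, o2);
                for (int xx = 0; xx < d1; ++xx) dst[2 * xx] = src[p + xx] + bval;
              }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                    NumericVector dy) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3], n = dims[4];
  const int cout = w.nrow() / 8;
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  const int o1 = 2 * d1, o2 = 2 * d2;
  const arma::uword onvox = nvox * 8;
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dW(w.nrow(), w.ncol(), arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx(x.size());
  arma::mat dB(nvox, 8 * (arma::uword)cout);
  for (int i = 0; i < n; ++i) {
    const double* dyi = dy.begin() + (arma::uword)i * onvox * cout;
    for (int co = 0; co < cout; ++co) {
      const double* oc = dyi + (arma::uword)co * onvox;
      for (int kz = 0; kz < 2; ++kz)
        for (int ky = 0; ky < 2; ++ky)
          for (int kx = 0; kx < 2; ++kx) {
            const arma::uword j = (arma::uword)(kx + 2 * ky + 4 * kz) + 8u * co;
            double* dst = dB.colptr(j);
            for (int z = 0; z < d3; ++z)
              for (int y = 0; y < d2; ++y) {
                const arma::uword p = spat_index(0, y, z, d1, d2);
                const double* src = oc + spat_index(kx, 2 * y + ky, 2 * z + kz, o1, o2);
                for (int xx = 0; xx < d1; ++xx) dst[p + xx] = src[2 * xx];
              }
          }
      db[co] += arma::accu(dB.cols(8u * co, 8u * co + 7));
    }
    arma::mat X(const_cast<double*>(x.begin()) + (arma::uword)i * nvox * cin,
                nvox, cin, false);
    arma::mat dX(dx.begin() + (arma::uword)i * nvox * cin, nvox, cin, false, true);
    dX = dB * W;
    dW += dB.t() * X;
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// 2x2x2 max pooling; returns pooled values and 0-based argmax into the input.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], c = dims[3], n = dims[4];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  const arma::uword onvox = (arma::uword)o1 * o2 * o3;
  NumericVector out(onvox * (arma::uword)c * n);
  IntegerVector arg(out.size());
  arma::uword oi = 0;
  for (int s = 0; s < c * n; ++s) {
    const double* xs = x.begin() + (arma::uword)s * nvox;
    const arma::uword base = (arma::uword)s * nvox;
    for (int z = 0; z < o3; ++z)
      for (int y = 0; y < o2; ++y)
        for (int xx = 0; xx < o1; ++xx) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bidx = 0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx) {
                const arma::uword idx = spat_index(2 * xx + kx, 2 * y + ky, 2 * z + kz, d1, d2);
                if (xs[idx] > best) { best = xs[idx]; bidx = idx; }
              }
          out[oi] = best;
          arg[oi] = (int)(base + bidx);
          ++oi;
        }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector arg, int xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[arg[i]] += dy[i];
  return dx;
}

// Sliding box sum along the three spatial axes (zero padding outside).
static void box_sum_axis(std::vector<double>& v, int d1, int d2, int d3,
                         arma::uword nrest, int axis, int h) {
  // process lines along `axis` for all other coordinates
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  int len, stride;
  if (axis == 0) { len = d1; stride = 1; }
  else if (axis == 1) { len = d2; stride = d1; }
  else { len = d3; stride = d1 * d2; }
  std::vector<double> line(len), pre(len + 1);
  for (arma::uword r = 0; r < nrest; ++r) {
    double* block = v.data() + r * nvox;
    // iterate over all lines in this block
    int o1, o2; // extents of the two non-axis dims
    if (axis == 0) { o1 = d2; o2 = d3; }
    else if (axis == 1) { o1 = d1; o2 = d3; }
    else { o1 = d1; o2 = d2; }
    for (int b = 0; b < o2; ++b)
      for (int a = 0; a < o1; ++a) {
        arma::uword start;
        if (axis == 0) start = spat_index(0, a, b, d1, d2);
        else if (axis == 1) start = spat_index(a, 0, b, d1, d2);
        else start = spat_index(a, b, 0, d1, d2);
        double* p = block + start;
        pre[0] = 0.0;
        for (int i = 0; i < len; ++i) pre[i + 1] = pre[i] + p[(arma::uword)i * stride];
        for (int i = 0; i < len; ++i) {
          const int lo = std::max(0, i - h), hi = std::min(len - 1, i + h);
          line[i] = pre[hi + 1] - pre[lo];
        }
        for (int i = 0; i < len; ++i) p[(arma::uword)i * stride] = line[i];
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_sum3(NumericVector x, IntegerVector dims, int h) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const arma::uword nrest = (arma::uword)dims[3] * dims[4];
  std::vector<double> v(x.begin(), x.end());
  box_sum_axis(v, d1, d2, d3, nrest, 0, h);
  box_sum_axis(v, d1, d2, d3, nrest, 1, h);
  box_sum_axis(v, d1, d2, d3, nrest, 2, h);
  return NumericVector(v.begin(), v.end());
}

// Window voxel counts (edge-truncated) as a full spatial grid.
// [[Rcpp::export]]
NumericVector cpp_box_counts(IntegerVector sdims, int h) {
  const int d1 = sdims[0], d2 = sdims[1], d3 = sdims[2];
  std::vector<double> c1(d1), c2(d2), c3(d3);
  for (int i = 0; i < d1; ++i) c1[i] = std::min(d1 - 1, i + h) - std::max(0, i - h) + 1;
  for (int i = 0; i < d2; ++i) c2[i] = std::min(d2 - 1, i + h) - std::max(0, i - h) + 1;
  for (int i = 0; i < d3; ++i) c3[i] = std::min(d3 - 1, i + h) - std::max(0, i - h) + 1;
  NumericVector out((arma::uword)d1 * d2 * d3);
  arma::uword p = 0;
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) out[p++] = c1[x] * c2[y] * c3[z];
  return out;
}

// Separable Gaussian smoothing with edge renormalisation (normalised convolution).
// sigma is in voxels, per axis; sigma <= 0 skips the axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector x, IntegerVector sdims, NumericVector sigma) {
  const int d[3] = { sdims[0], sdims[1], sdims[2] };
  std::vector<double> v(x.begin(), x.end());
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int h = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * h + 1);
    for (int i = -h; i <= h; ++i) kern[i + h] = std::exp(-0.5 * (i * i) / (s * s));
    const int len = d[axis];
    int stride = 1;
    for (int a = 0; a < axis; ++a) stride *= d[a];
    int o1, o2;
    if (axis == 0) { o1 = d[1]; o2 = d[2]; }
    else if (axis == 1) { o1 = d[0]; o2 = d[2]; }
    else { o1 = d[0]; o2 = d[1]; }
    std::vector<double> line(len);
    for (int b = 0; b < o2; ++b)
      for (int a = 0; a < o1; ++a) {
        arma::uword start;
        if (axis == 0) start = spat_index(0, a, b, d[0], d[1]);
        else if (axis == 1) start = spat_index(a, 0, b, d[0], d[1]);
        else start = spat_index(a, b, 0, d[0], d[1]);
        double* p = v.data() + start;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0, wsum = 0.0;
          const int lo = std::max(0, i - h), hi = std::min(len - 1, i + h);
          for (int j = lo; j <= hi; ++j) {
            const double w = kern[j - i + h];
            acc += w * p[(arma::uword)j * stride];
            wsum += w;
          }
          line[i] = acc / wsum;
        }
        for (int i = 0; i < len; ++i) p[(arma::uword)i * stride] = line[i];
      }
  }
  return NumericVector(v.begin(), v.end());
}

// For each row of A (physical coordinates), the distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
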