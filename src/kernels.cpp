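// Hot-path kernels: trilinear/nearest grid resampling and the 3D conv /
// max-pool / nearest-upsample primitives of the attention U-Net. Feature
// maps are R arrays dim (nx, ny, nz, C); column-major, x fastest, so the
// spatial volume flattens to an (nvox x C) matrix without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword vidx(int x, int y, int z, int nx, int ny) {
  return (arma::uword)x + (arma::uword)nx * ((arma::uword)y + (arma::uword)ny * (arma::uword)z);
}

// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector x, NumericVector old_spacing,
                                IntegerVector new_dims, NumericVector new_spacing,
                                bool nearest) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int mx = new_dims[0], my = new_dims[1], mz = new_dims[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  out.attr("dim") = new_dims;
  const double *src = x.begin();
  double *dst = out.begin();
  const double sx = new_spacing[0] / old_spacing[0];
  const double sy = new_spacing[1] / old_spacing[1];
  const double sz = new_spacing[2] / old_spacing[2];
  for (int k = 0; k < mz; ++k) {
    double w = k * sz;
    for (int j = 0; j < my; ++j) {
      double v = j * sy;
      for (int i = 0; i < mx; ++i) {
        double u = i * sx;
        double val;
        if (nearest) {
          int ui = (int)std::lround(u), vi = (int)std::lround(v), wi = (int)std::lround(w);
          ui = std::min(std::max(ui, 0), nx - 1);
          vi = std::min(std::max(vi, 0), ny - 1);
          wi = std::min(std::max(wi, 0), nz - 1);
          val = src[vidx(ui, vi, wi, nx, ny)];
        } else {
          double uc = std::min(std::max(u, 0.0), (double)(nx - 1));
          double vc = std::min(std::max(v, 0.0), (double)(ny - 1));
          double wc = std::min(std::max(w, 0.0), (double)(nz - 1));
          int u0 = std::min((int)uc, nx - 2 >= 0 ? nx - 2 : 0);
          int v0 = std::min((int)vc, ny - 2 >= 0 ? ny - 2 : 0);
          int w0 = std::min((int)wc, nz - 2 >= 0 ? nz - 2 : 0);
          if (nx == 1) u0 = 0;
          if (ny == 1) v0 = 0;
          if (nz == 1) w0 = 0;
          double fu = uc - u0, fv = vc - v0, fw = wc - w0;
          int u1 = std::min(u0 + 1, nx - 1), v1 = std::min(v0 + 1, ny - 1),
              w1 = std::min(w0 + 1, nz - 1);
          double c000 = src[vidx(u0, v0, w0, nx, ny)], c100 = src[vidx(u1, v0, w0, nx, ny)];
          double c010 = src[vidx(u0, v1, w0, nx, ny)], c110 = src[vidx(u1, v1, w0, nx, ny)];
          double c001 = src[vidx(u0, v0, w1, nx, ny)], c101 = src[vidx(u1, v0, w1, nx, ny)];
          double c011 = src[vidx(u0, v1, w1, nx, ny)], c111 = src[vidx(u1, v1, w1, nx, ny)];
          double c00 = c000 * (1 - fu) + c100 * fu, c10 = c010 * (1 - fu) + c110 * fu;
          double c01 = c001 * (1 - fu) + c101 * fu, c11 = c011 * (1 - fu) + c111 * fu;
          val = (c00 * (1 - fv) + c10 * fv) * (1 - fw) + (c01 * (1 - fv) + c11 * fv) * fw;
        }
        dst[vidx(i, j, k, mx, my)] = val;
      }
    }
  }
  return out;
}

// Shifted copy: out(v) = M(v + (dx,dy,dz)) inside bounds, else 0.
static void shift3(const arma::mat &M, arma::mat &out, int nx, int ny, int nz,
                   int dx, int dy, int dz) {
  out.zeros();
  const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx); // dest x-range
  if (x1 <= x0) return;
  const int len = x1 - x0;
  for (arma::uword c = 0; c < M.n_cols; ++c) {
    const double *s = M.colptr(c);
    double *t = out.colptr(c);
    for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z) {
      for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y) {
        arma::uword dv = vidx(x0, y, z, nx, ny);
        arma::uword sv = vidx(x0 + dx, y + dy, z + dz, nx, ny);
        std::memcpy(t + dv, s + sv, sizeof(double) * len);
      }
    }
  }
}

// Accumulating shifted add: out(v + (dx,dy,dz)) += M(v) inside bounds.
static void shift3_add(const arma::mat &M, arma::mat &out, int nx, int ny,
                       int nz, int dx, int dy, int dz) {
  const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
  if (x1 <= x0) return;
  const int len = x1 - x0;
  for (arma::uword c = 0; c < M.n_cols; ++c) {
    const double *s = M.colptr(c);
    double *t = out.colptr(c);
    for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z) {
      for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y) {
        arma::uword dv = vidx(x0, y, z, nx, ny);
        arma::uword sv = vidx(x0 + dx, y + dy, z + dz, nx, ny);
        const double *sp = s + dv;
        double *tp = t + sv;
        for (int i = 0; i < len; ++i) tp[i] += sp[i];
      }
    }
  }
}

// Reusable scratch buffers for the im2col matrices. Layers of different
// sizes alternate every call, so growing these monotonically avoids a large
// allocation (and page-zeroing) per convolution.
static std::vector<double> g_col_buf, g_dcol_buf;

static double *scratch(std::vector<double> &buf, arma::uword n) {
  if (buf.size() < n) buf.resize(n);
  return buf.data();
}

// im2col for a 3x3x3 neighbourhood: column block k (k = 0..26, offset
// (dx,dy,dz) = (k%3-1, (k/3)%3-1, k/9-1)) holds the input shifted by the
// offset, so that conv output = Col * W with W of shape (27*Cin) x Cout.
static void im2col27(const arma::mat &X, arma::mat &Col, int nx, int ny,
                     int nz) {
  const arma::uword nvox = X.n_rows, cin = X.n_cols;
  for (int k = 0; k < 27; ++k) {
    int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
    arma::mat block(Col.colptr((arma::uword)k * cin), nvox, cin, false, true);
    shift3(X, block, nx, ny, nz, dx, dy, dz);
  }
}

// 3x3x3 same-padding convolution via a single im2col GEMM.
// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, IntegerVector dims,
                        const arma::mat &W, const arma::vec &b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  const int cin = x.size() / nvox;
  const int cout = W.n_cols;
  arma::mat X(x.begin(), nvox, cin, false, true);
  arma::mat Col(scratch(g_col_buf, nvox * 27 * cin), nvox, 27 * cin,
                false, true);
  im2col27(X, Col, nx, ny, nz);
  NumericVector yv((R_xlen_t)nvox * cout);
  arma::mat Y(yv.begin(), nvox, cout, false, true);
  Y = Col * W;
  Y.each_row() += b.t();
  yv.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return yv;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector dy, IntegerVector dims,
               const arma::mat &W) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  const int cin = x.size() / nvox;
  const int cout = dy.size() / nvox;
  arma::mat X(x.begin(), nvox, cin, false, true);
  arma::mat DY(dy.begin(), nvox, cout, false, true);
  arma::mat Col(scratch(g_col_buf, nvox * 27 * cin), nvox, 27 * cin,
                false, true);
  im2col27(X, Col, nx, ny, nz);
  arma::mat dW = Col.t() * DY;
  arma::vec db = arma::sum(DY, 0).t();
  // dX = col2im(DY * W^T): scatter-add each offset block back
  arma::mat dCol(scratch(g_dcol_buf, nvox * 27 * cin), nvox, 27 * cin,
                 false, true);
  dCol = DY * W.t();
  NumericVector dxv((R_xlen_t)nvox * cin);
  arma::mat DX(dxv.begin(), nvox, cin, false, true);
  for (int k = 0; k < 27; ++k) {
    int dx = k % 3 - 1, dy_ = (k / 3) % 3 - 1, dz = k / 9 - 1;
    arma::mat block(dCol.colptr((arma::uword)k * cin), nvox, cin, false, true);
    shift3_add(block, DX, nx, ny, nz, dx, dy_, dz);
  }
  dxv.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling (dims must be even). Returns pooled map and the 0-based
// linear spatial index of each argmax for the backward pass.
// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  const int C = x.size() / nvox;
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const arma::uword ovox = (arma::uword)ox * oy * oz;
  NumericVector yv((R_xlen_t)ovox * C);
  IntegerVector iv((R_xlen_t)ovox * C);
  const double *src = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *s = src + (arma::uword)c * nvox;
    double *t = yv.begin() + (arma::uword)c * ovox;
    int *ti = iv.begin() + (arma::uword)c * ovox;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          double best = -1e300; arma::uword bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                arma::uword v = vidx(2 * xo + dx, 2 * y + dy, 2 * z + dz, nx, ny);
                if (s[v] > best) { best = s[v]; bi = v; }
              }
          arma::uword o = vidx(xo, y, z, ox, oy);
          t[o] = best; ti[o] = (int)bi;
        }
  }
  yv.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  iv.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(_["y"] = yv, _["idx"] = iv);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector dy, IntegerVector idx, IntegerVector in_dims) {
  const int nx = in_dims[0], ny = in_dims[1], nz = in_dims[2];
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  IntegerVector od = dy.attr("dim");
  const arma::uword ovox = (arma::uword)od[0] * od[1] * od[2];
  const int C = od[3];
  NumericVector dxv((R_xlen_t)nvox * C);
  for (int c = 0; c < C; ++c) {
    const double *s = dy.begin() + (arma::uword)c * ovox;
    const int *si = idx.begin() + (arma::uword)c * ovox;
    double *t = dxv.begin() + (arma::uword)c * nvox;
    for (arma::uword o = 0; o < ovox; ++o) t[si[o]] += s[o];
  }
  dxv.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  return dxv;
}

// Nearest-neighbour x2 upsampling and its adjoint.
// [[Rcpp::export]]
NumericVector upsample3d_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  const arma::uword mvox = (arma::uword)mx * my * mz;
  NumericVector yv((R_xlen_t)mvox * C);
  for (int c = 0; c < C; ++c) {
    const double *s = x.begin() + (arma::uword)c * nvox;
    double *t = yv.begin() + (arma::uword)c * mvox;
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y) {
        arma::uword srow = vidx(0, y / 2, z / 2, nx, ny);
        arma::uword trow = vidx(0, y, z, mx, my);
        for (int xo = 0; xo < mx; ++xo) t[trow + xo] = s[srow + xo / 2];
      }
  }
  yv.attr("dim") = IntegerVector::create(mx, my, mz, C);
  return yv;
}

// [[Rcpp::export]]
NumericVector upsample3d_bw(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int mx = d[0], my = d[1], mz = d[2], C = d[3];
  const int nx = mx / 2, ny = my / 2, nz = mz / 2;
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  const arma::uword mvox = (arma::uword)mx * my * mz;
  NumericVector dxv((R_xlen_t)nvox * C);
  for (int c = 0; c < C; ++c) {
    const double *s = dy.begin() + (arma::uword)c * mvox;
    double *t = dxv.begin() + (arma::uword)c * nvox;
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y) {
        arma::uword srow = vidx(0, y, z, mx, my);
        arma::uword trow = vidx(0, y / 2, z / 2, nx, ny);
        for (int xo = 0; xo < mx; ++xo) t[trow + xo / 2] += s[srow + xo];
      }
  }
  dxv.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  return dxv;
}

// Per-class 26(/18/6)-neighbour label counts used by the morphological
// post-processing steps: counts[v, c] = number of neighbours of v (under the
// given connectivity) whose label equals cls[c].
// [[Rcpp::export]]
IntegerVector neighbor_label_counts(IntegerVector lab, IntegerVector dims,
                                    IntegerVector cls, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  const int nc = cls.size();
  IntegerVector out((R_xlen_t)nvox * nc);
  const int *L = lab.begin();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z)
          for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y)
            for (int x0 = std::max(0, -dx); x0 < std::min(nx, nx - dx); ++x0) {
              int nb = L[vidx(x0 + dx, y + dy, z + dz, nx, ny)];
              for (int c = 0; c < nc; ++c)
                if (nb == cls[c]) {
                  out[(arma::uword)c * nvox + vidx(x0, y, z, nx, ny)] += 1;
                  break;
                }
            }
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return out;
}
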