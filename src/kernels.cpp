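#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored as C x (B*N) matrices: one column per voxel,
// samples concatenated along columns, voxels in column-major spatial
// order (first axis fastest). All kernels support 2D and 3D grids via
// the length of `dims`.

static inline void get_dims(const IntegerVector& dims, int* d, int* nd) {
  *nd = dims.size();
  for (int i = 0; i < *nd; ++i) d[i] = dims[i];
  if (*nd == 2) d[2] = 1;
}

// Unfold 3x3(x3) neighbourhoods (stride 1, zero padding 1) into rows:
// output is (C*K) x (B*N) with K = 3^d, kernel offsets column-major.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerVector& dims,
                         int B) {
  int d[3], nd;
  get_dims(dims, d, &nd);
  const int C = X.nrow();
  const int N = d[0] * d[1] * d[2];
  if (X.ncol() != (R_xlen_t)B * N) stop("im2col: column count mismatch");
  const int kzlo = (nd == 3) ? -1 : 0, kzhi = (nd == 3) ? 1 : 0;
  const int K = (nd == 3) ? 27 : 9;
  NumericMatrix out(C * K, (R_xlen_t)B * N);
  const double* xp = REAL(X);
  double* op = REAL(out);
  const R_xlen_t ocr = (R_xlen_t)C * K;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t base = (R_xlen_t)b * N;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const R_xlen_t p = base + x + (R_xlen_t)d[0] * (y + (R_xlen_t)d[1] * z);
          double* oc = op + p * ocr;
          for (int kz = kzlo; kz <= kzhi; ++kz)
            for (int ky = -1; ky <= 1; ++ky)
              for (int kx = -1; kx <= 1; ++kx, oc += C) {
                const int xx = x + kx, yy = y + ky, zz = z + kz;
                if (xx < 0 || xx >= d[0] || yy < 0 || yy >= d[1] ||
                    zz < 0 || zz >= d[2]) {
                  for (int c = 0; c < C; ++c) oc[c] = 0.0;
                } else {
                  const double* sc = xp +
                    (base + xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz)) * C;
                  for (int c = 0; c < C; ++c) oc[c] = sc[c];
                }
              }
        }
  }
  return out;
}

// Adjoint of cpp_im2col: fold (C*K) x (B*N) gradients back onto the
// C x (B*N) input grid with accumulation.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcol, const IntegerVector& dims,
                         int B) {
  int d[3], nd;
  get_dims(dims, d, &nd);
  const int N = d[0] * d[1] * d[2];
  const int kzlo = (nd == 3) ? -1 : 0, kzhi = (nd == 3) ? 1 : 0;
  const int K = (nd == 3) ? 27 : 9;
  const int C = dcol.nrow() / K;
  if (C * K != dcol.nrow()) stop("col2im: row count not divisible by K");
  if (dcol.ncol() != (R_xlen_t)B * N) stop("col2im: column count mismatch");
  NumericMatrix dX(C, (R_xlen_t)B * N);
  const double* gp = REAL(dcol);
  double* xp = REAL(dX);
  const R_xlen_t gcr = (R_xlen_t)C * K;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t base = (R_xlen_t)b * N;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const R_xlen_t p = base + x + (R_xlen_t)d[0] * (y + (R_xlen_t)d[1] * z);
          const double* gc = gp + p * gcr;
          for (int kz = kzlo; kz <= kzhi; ++kz)
            for (int ky = -1; ky <= 1; ++ky)
              for (int kx = -1; kx <= 1; ++kx, gc += C) {
                const int xx = x + kx, yy = y + ky, zz = z + kz;
                if (xx < 0 || xx >= d[0] || yy < 0 || yy >= d[1] ||
                    zz < 0 || zz >= d[2]) continue;
                double* tc = xp +
                  (base + xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz)) * C;
                for (int c = 0; c < C; ++c) tc[c] += gc[c];
              }
        }
  }
  return dX;
}

// 2^d max pooling with stride 2; returns pooled values and, per output
// element, the flat source column index (1-based) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericMatrix& X, const IntegerVector& dims, int B) {
  int d[3], nd;
  get_dims(dims, d, &nd);
  const int C = X.nrow();
  const int N = d[0] * d[1] * d[2];
  if (X.ncol() != (R_xlen_t)B * N) stop("maxpool: column count mismatch");
  int od[3] = { d[0] / 2, d[1] / 2, (nd == 3) ? d[2] / 2 : 1 };
  if (od[0] * 2 != d[0] || od[1] * 2 != d[1] ||
      (nd == 3 && od[2] * 2 != d[2]))
    stop("maxpool: spatial dimensions must be even");
  const int M = od[0] * od[1] * od[2];
  NumericMatrix Y(C, (R_xlen_t)B * M);
  IntegerMatrix idx(C, (R_xlen_t)B * M);
  const double* xp = REAL(X);
  double* yp = REAL(Y);
  int* ip = INTEGER(idx);
  const int czhi = (nd == 3) ? 1 : 0;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t ibase = (R_xlen_t)b * N, obase = (R_xlen_t)b * M;
    for (int z = 0; z < od[2]; ++z)
      for (int y = 0; y < od[1]; ++y)
        for (int x = 0; x < od[0]; ++x) {
          const R_xlen_t q = obase + x + (R_xlen_t)od[0] * (y + (R_xlen_t)od[1] * z);
          double* yc = yp + q * C;
          int* ic = ip + q * C;
          bool first = true;
          for (int cz = 0; cz <= czhi; ++cz)
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                const R_xlen_t src = ibase + (2 * x + cx) +
                  (R_xlen_t)d[0] * ((2 * y + cy) + (R_xlen_t)d[1] * (2 * z + cz));
                const double* sc = xp + src * C;
                if (first) {
                  for (int c = 0; c < C; ++c) { yc[c] = sc[c]; ic[c] = (int)src + 1; }
                  first = false;
                } else {
                  for (int c = 0; c < C; ++c)
                    if (sc[c] > yc[c]) { yc[c] = sc[c]; ic[c] = (int)src + 1; }
                }
              }
        }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// Route pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(const NumericMatrix& dY, const IntegerMatrix& idx,
                             int ncol_in) {
  const int C = dY.nrow();
  NumericMatrix dX(C, ncol_in);
  const double* gp = REAL(dY);
  const int* ip = INTEGER(idx);
  double* xp = REAL(dX);
  const R_xlen_t M = dY.ncol();
  for (R_xlen_t q = 0; q < M; ++q)
    for (int c = 0; c < C; ++c)
      xp[(R_xlen_t)(ip[q * C + c] - 1) * C + c] += gp[q * C + c];
  return dX;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping): scatter
// G = (Cout*K2) x (B*N) kernel-offset blocks onto the doubled grid.
// Offset order is column-major over the 2^d kernel positions.
// [[Rcpp::export]]
NumericMatrix cpp_up2_scatter(const NumericMatrix& G, const IntegerVector& dims,
                              int B, int Cout) {
  int d[3], nd;
  get_dims(dims, d, &nd);
  const int N = d[0] * d[1] * d[2];
  const int K2 = (nd == 3) ? 8 : 4;
  if (G.nrow() != Cout * K2) stop("up2: row count mismatch");
  if (G.ncol() != (R_xlen_t)B * N) stop("up2: column count mismatch");
  int od[3] = { 2 * d[0], 2 * d[1], (nd == 3) ? 2 * d[2] : 1 };
  const int M = od[0] * od[1] * od[2];
  NumericMatrix Y(Cout, (R_xlen_t)B * M);
  const double* gp = REAL(G);
  double* yp = REAL(Y);
  const int ozhi = (nd == 3) ? 1 : 0;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t ibase = (R_xlen_t)b * N, obase = (R_xlen_t)b * M;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const R_xlen_t p = ibase + x + (R_xlen_t)d[0] * (y + (R_xlen_t)d[1] * z);
          const double* gc = gp + p * (R_xlen_t)Cout * K2;
          int k = 0;
          for (int oz = 0; oz <= ozhi; ++oz)
            for (int oy = 0; oy <= 1; ++oy)
              for (int ox = 0; ox <= 1; ++ox, ++k) {
                const R_xlen_t dst = obase + (2 * x + ox) +
                  (R_xlen_t)od[0] * ((2 * y + oy) + (R_xlen_t)od[1] * (2 * z + oz));
                double* yc = yp + dst * Cout;
                const double* gk = gc + (R_xlen_t)k * Cout;
                for (int c = 0; c < Cout; ++c) yc[c] = gk[c];
              }
        }
  }
  return Y;
}

// Adjoint of cpp_up2_scatter: gather gradients from the fine grid into
// kernel-offset blocks on the coarse grid.
// [[Rcpp::export]]
NumericMatrix cpp_up2_gather(const NumericMatrix& dY, const IntegerVector& dims,
                             int B, int Cout) {
  int d[3], nd;
  get_dims(dims, d, &nd);
  const int N = d[0] * d[1] * d[2];
  const int K2 = (nd == 3) ? 8 : 4;
  int od[3] = { 2 * d[0], 2 * d[1], (nd == 3) ? 2 * d[2] : 1 };
  const int M = od[0] * od[1] * od[2];
  if (dY.nrow() != Cout) stop("up2 gather: row count mismatch");
  if (dY.ncol() != (R_xlen_t)B * M) stop("up2 gather: column count mismatch");
  NumericMatrix G(Cout * K2, (R_xlen_t)B * N);
  const double* yp = REAL(dY);
  double* gp = REAL(G);
  const int ozhi = (nd == 3) ? 1 : 0;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t ibase = (R_xlen_t)b * N, obase = (R_xlen_t)b * M;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const R_xlen_t p = ibase + x + (R_xlen_t)d[0] * (y + (R_xlen_t)d[1] * z);
          double* gc = gp + p * (R_xlen_t)Cout * K2;
          int k = 0;
          for (int oz = 0; oz <= ozhi; ++oz)
            for (int oy = 0; oy <= 1; ++oy)
              for (int ox = 0; ox <= 1; ++ox, ++k) {
                const R_xlen_t src = obase + (2 * x + ox) +
                  (R_xlen_t)od[0] * ((2 * y + oy) + (R_xlen_t)od[1] * (2 * z + oz));
                const double* yc = yp + src * Cout;
                double* gk = gc + (R_xlen_t)k * Cout;
                for (int c = 0; c < Cout; ++c) gk[c] = yc[c];
              }
        }
  }
  return G;
}
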