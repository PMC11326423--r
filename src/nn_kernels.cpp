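// 3D convolution and max-pooling kernels for the volumetric regressors.
//
// Data layout: a batch is a dense matrix with one column per sample; within
// a column, the x index varies fastest, then y, then z, then channel
// (channel-major blocks of V = nx*ny*nz). Convolution is im2col + GEMM with
// the patch matrix laid out V x (C*k^3) so patch extraction writes
// contiguous runs and the GEMM output is already in the batch layout.
// Convolutions use odd kernels with "same" zero padding; pooling is 2^3
// windows with stride 2 and floor semantics (axes of extent 1 pass through).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col3d(const double* x, mat& P, int nx, int ny, int nz, int C, int k) {
  const int pad = (k - 1) / 2;
  const int V = nx * ny * nz;
  P.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * V;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int q = c * k * k * k + (dz * k + dy) * k + dx;
          double* Pq = P.colptr(q);
          const int i0 = std::max(0, pad - dx);
          const int i1 = std::min(nx, nx + pad - dx);
          if (i1 <= i0) continue;
          for (int kk = 0; kk < nz; ++kk) {
            const int sz = kk + dz - pad;
            if (sz < 0 || sz >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int sy = j + dy - pad;
              if (sy < 0 || sy >= ny) continue;
              const double* src = xc + ((std::size_t)sz * ny + sy) * nx + (i0 + dx - pad);
              double* dst = Pq + ((std::size_t)kk * ny + j) * nx + i0;
              std::memcpy(dst, src, (i1 - i0) * sizeof(double));
            }
          }
        }
  }
}

static void col2im3d_add(double* x, const mat& dP, int nx, int ny, int nz, int C, int k) {
  const int pad = (k - 1) / 2;
  const int V = nx * ny * nz;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * V;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int q = c * k * k * k + (dz * k + dy) * k + dx;
          const double* Pq = dP.colptr(q);
          const int i0 = std::max(0, pad - dx);
          const int i1 = std::min(nx, nx + pad - dx);
          if (i1 <= i0) continue;
          for (int kk = 0; kk < nz; ++kk) {
            const int sz = kk + dz - pad;
            if (sz < 0 || sz >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int sy = j + dy - pad;
              if (sy < 0 || sy >= ny) continue;
              double* dst = xc + ((std::size_t)sz * ny + sy) * nx + (i0 + dx - pad);
              const double* src = Pq + ((std::size_t)kk * ny + j) * nx + i0;
              for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
            }
          }
        }
  }
}

// [[Rcpp::export]]
arma::mat conv3d_fwd(const arma::mat& X, const arma::mat& W, const arma::vec& b,
                     int nx, int ny, int nz, int Cin, int k) {
  const int V = nx * ny * nz;
  const int B = X.n_cols;
  const int Cout = W.n_cols;
  if ((int)W.n_rows != Cin * k * k * k || (int)X.n_rows != V * Cin)
    Rcpp::stop("conv3d_fwd: shape mismatch");
  mat Y(V * Cout, B);
  mat P(V, Cin * k * k * k);
  for (int s = 0; s < B; ++s) {
    im2col3d(X.colptr(s), P, nx, ny, nz, Cin, k);
    mat Ys = P * W; // V x Cout
    Ys.each_row() += b.t();
    std::memcpy(Y.colptr(s), Ys.memptr(), (std::size_t)V * Cout * sizeof(double));
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd(const arma::mat& X, const arma::mat& W, const arma::mat& dY,
                      int nx, int ny, int nz, int Cin, int k) {
  const int V = nx * ny * nz;
  const int B = X.n_cols;
  const int Cout = W.n_cols;
  mat dX(size(X), fill::zeros);
  mat dW(size(W), fill::zeros);
  vec db(Cout, fill::zeros);
  mat P(V, Cin * k * k * k);
  for (int s = 0; s < B; ++s) {
    im2col3d(X.colptr(s), P, nx, ny, nz, Cin, k);
    const mat dYs(const_cast<double*>(dY.colptr(s)), V, Cout, false, true);
    dW += P.t() * dYs;
    db += sum(dYs, 0).t();
    mat dP = dYs * W.t(); // V x Cin*k^3
    col2im3d_add(dX.colptr(s), dP, nx, ny, nz, Cin, k);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool3d_fwd(const arma::mat& X, int nx, int ny, int nz, int C) {
  const int V = nx * ny * nz;
  const int B = X.n_cols;
  const int ox = nx >= 2 ? nx / 2 : 1;
  const int oy = ny >= 2 ? ny / 2 : 1;
  const int oz = nz >= 2 ? nz / 2 : 1;
  const int wx = nx >= 2 ? 2 : 1, wy = ny >= 2 ? 2 : 1, wz = nz >= 2 ? 2 : 1;
  const int Vo = ox * oy * oz;
  mat Y(Vo * C, B);
  imat A(Vo * C, B); // argmax row index within the input column
  for (int s = 0; s < B; ++s) {
    const double* xs = X.colptr(s);
    double* ys = Y.colptr(s);
    int* as = A.colptr(s);
    for (int c = 0; c < C; ++c) {
      const std::size_t ci = (std::size_t)c * V;
      const std::size_t co = (std::size_t)c * Vo;
      for (int kk = 0; kk < oz; ++kk)
        for (int j = 0; j < oy; ++j)
          for (int i = 0; i < ox; ++i) {
            double best = -datum::inf;
            std::size_t besti = 0;
            for (int dz = 0; dz < wz; ++dz)
              for (int dy = 0; dy < wy; ++dy)
                for (int dx = 0; dx < wx; ++dx) {
                  const std::size_t idx = ci +
                    ((std::size_t)(2 * kk + dz) * ny + (2 * j + dy)) * nx + (2 * i + dx);
                  if (xs[idx] > best) { best = xs[idx]; besti = idx; }
                }
            const std::size_t out = co + ((std::size_t)kk * oy + j) * ox + i;
            ys[out] = best;
            as[out] = (int)besti;
          }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("argmax") = A,
                            Rcpp::Named("out_dims") = Rcpp::IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export]]
arma::mat maxpool3d_bwd(const arma::mat& dY, const arma::imat& argmax, int in_rows) {
  const int B = dY.n_cols;
  mat dX(in_rows, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const double* dys = dY.colptr(s);
    const int* as = argmax.colptr(s);
    double* dxs = dX.colptr(s);
    for (uword r = 0; r < dY.n_rows; ++r) dxs[as[r]] += dys[r];
  }
  return dX;
}
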