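// Low-level numeric kernels for the 3D dense U-net and instance labeling.
//
// Voxel layout convention (shared with the R side): a volume of dims
// (nz, ny, nx) is stored column-major as an R array indexed [z, y, x], so the
// 0-based linear index of voxel (z, y, x) is  v = z + nz*(y + ny*x).
// Feature tensors are (channels x n_voxels) matrices whose columns follow the
// same linear order; 3x3x3 convolution is computed as 27 shifted GEMMs
// against a precomputed neighbor-index table (out-of-bounds = -1 = zero pad).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Zero the columns of M whose voxel would read out of bounds under the
// stencil offset (dz, dy, dx). Out-of-bounds voxels form axis-aligned
// boundary slabs, addressable as short contiguous column runs.
static void zero_oob_cols(arma::fmat& M, int dz, int dy, int dx,
                          int nz, int ny, int nx) {
  if (dz != 0) {                      // one z plane per (y, x) column block
    const int z = (dz < 0) ? 0 : nz - 1;
    for (int j = z; j < nz * ny * nx; j += nz) M.col(j).zeros();
  }
  if (dy != 0) {                      // one y row: nz-long runs per x
    const int y = (dy < 0) ? 0 : ny - 1;
    for (int x = 0; x < nx; ++x) {
      const int j0 = nz * (y + ny * x);
      M.cols(j0, j0 + nz - 1).zeros();
    }
  }
  if (dx != 0) {                      // one x slab: a single contiguous run
    const int x = (dx < 0) ? 0 : nx - 1;
    const int j0 = nz * ny * x;
    M.cols(j0, j0 + nz * ny - 1).zeros();
  }
}

// Fast shifted gather: with z-fastest layout the in-bounds part of the
// stencil shift is one contiguous block copy; boundary columns are zeroed.
static void gather_shift(arma::fmat& G, const arma::fmat& X,
                         int dz, int dy, int dx, int nz, int ny, int nx) {
  const int N = nz * ny * nx;
  const int off = dz + nz * (dy + ny * dx);
  const int lo = std::max(0, -off), hi = N - 1 - std::max(0, off);
  if (lo > hi) { G.zeros(); return; }
  G.cols(lo, hi) = X.cols(lo + off, hi + off);
  if (lo > 0) G.cols(0, lo - 1).zeros();
  if (hi < N - 1) G.cols(hi + 1, N - 1).zeros();
  zero_oob_cols(G, dz, dy, dx, nz, ny, nx);
}

// Convolution arithmetic runs in single precision (the standard working
// precision for CNN training); inputs and results cross the R boundary as
// doubles.
static arma::fmat to_f(const arma::mat& X) {
  return arma::conv_to<arma::fmat>::from(X);
}
static arma::fcube to_f(const arma::cube& X) {
  return arma::conv_to<arma::fcube>::from(X);
}

// Forward 3x3x3 convolution (zero padding, stride 1).
// X: Cin x N, W: Cout x Cin x 27 cube, b: Cout, dims: (nz, ny, nx) with
// nz*ny*nx = N. Returns Cout x N. Weight slice order follows the nested
// (dx, dy, dz) offset loop and is shared with the backward pass.
// [[Rcpp::export]]
arma::mat conv3d_fw_cpp(const arma::mat& X, const arma::cube& W,
                        const arma::vec& b, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int N = X.n_cols;
  arma::fmat Xf = to_f(X);
  arma::fcube Wf = to_f(W);
  arma::fvec bf = arma::conv_to<arma::fvec>::from(b);
  arma::fmat Y(W.n_rows, N, arma::fill::zeros);
  arma::fmat G(X.n_rows, N);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz, ++k) {
        gather_shift(G, Xf, dz, dy, dx, nz, ny, nx);
        Y += Wf.slice(k) * G;
      }
  Y.each_col() += bf;
  return arma::conv_to<arma::mat>::from(Y);
}

// Backward pass: returns gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv3d_bw_cpp(const arma::mat& X, const arma::mat& dY,
                   const arma::cube& W, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int N = X.n_cols;
  arma::fmat Xf = to_f(X);
  arma::fmat dYf = to_f(dY);
  arma::fcube Wf = to_f(W);
  arma::fmat dX(X.n_rows, N, arma::fill::zeros);
  arma::fcube dW(W.n_rows, W.n_cols, 27);
  arma::fmat G(X.n_rows, N);
  arma::fmat T(W.n_cols, N);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz, ++k) {
        gather_shift(G, Xf, dz, dy, dx, nz, ny, nx);
        dW.slice(k) = dYf * G.t();
        // Y[, j] += W_k X[, j+off]  =>  dX[, j+off] += W_k^T dY[, j]
        T = Wf.slice(k).t() * dYf;
        zero_oob_cols(T, dz, dy, dx, nz, ny, nx);
        const int off = dz + nz * (dy + ny * dx);
        const int lo = std::max(0, -off), hi = N - 1 - std::max(0, off);
        if (lo <= hi)
          dX.cols(lo + off, hi + off) += T.cols(lo, hi);
      }
  arma::vec db = arma::conv_to<arma::vec>::from(arma::sum(dYf, 1));
  return List::create(_["dX"] = arma::conv_to<arma::mat>::from(dX),
                      _["dW"] = arma::conv_to<arma::cube>::from(dW),
                      _["db"] = db);
}

// 2x2x2 max pooling over the voxel grid; per-channel argmax retained for the
// backward pass. dims must be even along every axis (checked on the R side).
// [[Rcpp::export]]
List maxpool3d_fw_cpp(const arma::mat& X, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  const int C = X.n_rows, No = oz * oy * ox;
  arma::mat Y(C, No);
  IntegerMatrix arg(C, No);  // 0-based input linear index of the max
  int vo = 0;
  for (int x = 0; x < ox; ++x) {
    for (int y = 0; y < oy; ++y) {
      for (int z = 0; z < oz; ++z, ++vo) {
        int child[8];
        int m = 0;
        for (int ddx = 0; ddx < 2; ++ddx)
          for (int ddy = 0; ddy < 2; ++ddy)
            for (int ddz = 0; ddz < 2; ++ddz)
              child[m++] = (2 * z + ddz) + nz * ((2 * y + ddy) + ny * (2 * x + ddx));
        for (int c = 0; c < C; ++c) {
          double best = X(c, child[0]);
          int bi = child[0];
          for (int t = 1; t < 8; ++t) {
            const double val = X(c, child[t]);
            if (val > best) { best = val; bi = child[t]; }
          }
          Y(c, vo) = best;
          arg(c, vo) = bi;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = arg);
}

// [[Rcpp::export]]
arma::mat maxpool3d_bw_cpp(const arma::mat& dY, const IntegerMatrix& arg, int n_in) {
  const int C = dY.n_rows, No = dY.n_cols;
  arma::mat dX(C, n_in, arma::fill::zeros);
  for (int j = 0; j < No; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, arg(c, j)) += dY(c, j);
  return dX;
}

// Connected-component labeling of a binary foreground on the (nz, ny, nx)
// grid; 26-connectivity by default, 6-connectivity otherwise. Iterative BFS.
// Returns integer labels 1..n_components (0 = background) in voxel order.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(const IntegerVector& fg, IntegerVector dims, bool diag26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int N = nz * ny * nx;
  IntegerVector lab(N, 0);
  std::vector<int> stack;
  int next = 0;
  for (int seed = 0; seed < N; ++seed) {
    if (fg[seed] == 0 || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int z = v % nz, y = (v / nz) % ny, x = v / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (!diag26 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) > 1) continue;
            const int zs = z + dz, ys = y + dy, xs = x + dx;
            if (zs < 0 || zs >= nz || ys < 0 || ys >= ny || xs < 0 || xs >= nx) continue;
            const int w = zs + nz * (ys + ny * xs);
            if (fg[w] != 0 && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}
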