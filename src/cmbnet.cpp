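// Low-level kernels for the 3D patch classifier: im2col-based 3x3x3
// convolution (forward/backward) and 2x2x2 max pooling. Activations are
// stored as (channels * voxels) x batch matrices, voxel index fastest
// within each channel block; voxels are in R array (column-major) order.
//
// Neighbour tables are precomputed in R per spatial shape:
//   nb:   V x 27 integer matrix, 0-based input voxel index per tap, -1 = pad
//   pmap: Vout x 8 integer matrix, 0-based input voxel per pooling window
//         slot, -1 = outside (floor pooling drops trailing voxels)
// Weight layout: W is Cout x (Cin*27), column k = cin*27 + tap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const arma::mat& X, int s, const IntegerMatrix& nb,
                   int Cin, int V, arma::mat& col) {
  // col: (Cin*27) x V
  const double* xs = X.colptr(s);
  for (int v = 0; v < V; ++v) {
    for (int t = 0; t < 27; ++t) {
      int idx = nb(v, t);
      if (idx < 0) {
        for (int c = 0; c < Cin; ++c) col(c * 27 + t, v) = 0.0;
      } else {
        for (int c = 0; c < Cin; ++c) col(c * 27 + t, v) = xs[c * V + idx];
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
arma::mat conv3d_fwd(const arma::mat& X, const arma::mat& W,
                     const arma::vec& b, const IntegerMatrix& nb, int Cin) {
  const int V = nb.nrow();
  const int B = X.n_cols;
  const int Cout = W.n_rows;
  arma::mat Y(Cout * V, B);
  arma::mat col(Cin * 27, V);
  for (int s = 0; s < B; ++s) {
    im2col(X, s, nb, Cin, V, col);
    arma::mat Ym = W * col;          // Cout x V
    Ym.each_col() += b;
    double* ys = Y.colptr(s);
    for (int c = 0; c < Cout; ++c)
      for (int v = 0; v < V; ++v) ys[c * V + v] = Ym(c, v);
  }
  return Y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(const arma::mat& X, const arma::mat& W, const arma::mat& dY,
                const IntegerMatrix& nb, int Cin) {
  const int V = nb.nrow();
  const int B = X.n_cols;
  const int Cout = W.n_rows;
  arma::mat dX(X.n_rows, B, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(Cin * 27, V);
  arma::mat dYm(Cout, V);
  for (int s = 0; s < B; ++s) {
    im2col(X, s, nb, Cin, V, col);
    const double* dys = dY.colptr(s);
    for (int c = 0; c < Cout; ++c)
      for (int v = 0; v < V; ++v) dYm(c, v) = dys[c * V + v];
    dW += dYm * col.t();
    db += arma::sum(dYm, 1);
    arma::mat dcol = W.t() * dYm;    // (Cin*27) x V
    double* dxs = dX.colptr(s);
    for (int v = 0; v < V; ++v) {
      for (int t = 0; t < 27; ++t) {
        int idx = nb(v, t);
        if (idx < 0) continue;
        for (int c = 0; c < Cin; ++c)
          dxs[c * V + idx] += dcol(c * 27 + t, v);
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::mat& X, const IntegerMatrix& pmap,
                 int C, int Vin) {
  const int Vout = pmap.nrow();
  const int B = X.n_cols;
  arma::mat Y(C * Vout, B);
  IntegerMatrix amax(C * Vout, B);   // winning input voxel index, 0-based
  for (int s = 0; s < B; ++s) {
    const double* xs = X.colptr(s);
    double* ys = Y.colptr(s);
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)c * Vin;
      for (int v = 0; v < Vout; ++v) {
        double best = -std::numeric_limits<double>::infinity();
        int bidx = -1;
        for (int t = 0; t < 8; ++t) {
          int idx = pmap(v, t);
          if (idx < 0) continue;
          double val = xc[idx];
          if (val > best) { best = val; bidx = idx; }
        }
        ys[c * Vout + v] = best;
        amax(c * Vout + v, s) = bidx;
      }
    }
  }
  return List::create(Named("Y") = Y, Named("amax") = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::mat maxpool_bwd(const arma::mat& dY, const IntegerMatrix& amax,
                      int C, int Vin) {
  const int Vout = dY.n_rows / C;
  const int B = dY.n_cols;
  arma::mat dX(C * Vin, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const double* dys = dY.colptr(s);
    double* dxs = dX.colptr(s);
    for (int c = 0; c < C; ++c)
      for (int v = 0; v < Vout; ++v) {
        int idx = amax(c * Vout + v, s);
        if (idx >= 0) dxs[(size_t)c * Vin + idx] += dys[c * Vout + v];
      }
  }
  return dX;
}
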