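// Numeric hot loops for the PIV engine and the phantom renderer.
// Everything here is deliberately dumb and allocation-light; the
// surrounding logic (scheduling, validation, unit handling) lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Ensemble cross-correlation of paired interrogation windows.
// A, B: n x n x k cubes (k cycles of the same phase), already
// mean-subtracted and apodized. Correlation is computed in the Fourier
// domain with zero-padding to `pad` (>= 2n to avoid periodic aliasing),
// spectra are accumulated over the k slices, and a single inverse
// transform yields the ensemble-averaged plane, fftshifted so that zero
// displacement sits at (pad/2 + 1, pad/2 + 1) in R's 1-based indexing.
// [[Rcpp::export]]
arma::mat cpp_xcorr_ensemble(const arma::cube& A, const arma::cube& B, int pad) {
  const arma::uword n = A.n_rows;
  const arma::uword k = A.n_slices;
  arma::cx_mat acc(pad, pad, arma::fill::zeros);
  arma::mat Ap(pad, pad), Bp(pad, pad);
  for (arma::uword s = 0; s < k; ++s) {
    Ap.zeros(); Bp.zeros();
    Ap.submat(0, 0, n - 1, n - 1) = A.slice(s);
    Bp.submat(0, 0, n - 1, n - 1) = B.slice(s);
    acc += arma::conj(arma::fft2(Ap)) % arma::fft2(Bp);
  }
  arma::mat plane = arma::real(arma::ifft2(acc)) / double(k);
  // fftshift both dimensions (pad is even by construction)
  const int h = pad / 2;
  arma::mat out(pad, pad);
  out.submat(0, 0, h - 1, h - 1)       = plane.submat(h, h, pad - 1, pad - 1);
  out.submat(h, h, pad - 1, pad - 1)   = plane.submat(0, 0, h - 1, h - 1);
  out.submat(0, h, h - 1, pad - 1)     = plane.submat(h, 0, pad - 1, h - 1);
  out.submat(h, 0, pad - 1, h - 1)     = plane.submat(0, h, h - 1, pad - 1);
  return out;
}

// Bilinear sampling of an image at fractional pixel coordinates.
// X, Y are 0-based column/row coordinates; samples outside the image are
// clamped to the border (constant extension).
// [[Rcpp::export]]
arma::mat cpp_bilinear(const arma::mat& img, const arma::mat& X, const arma::mat& Y) {
  const int nr = img.n_rows, nc = img.n_cols;
  arma::mat out(X.n_rows, X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      double x = X(i, j), y = Y(i, j);
      if (x < 0) x = 0; if (x > nc - 1) x = nc - 1;
      if (y < 0) y = 0; if (y > nr - 1) y = nr - 1;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      int x1 = std::min(x0 + 1, nc - 1), y1 = std::min(y0 + 1, nr - 1);
      double fx = x - x0, fy = y - y0;
      out(i, j) = img(y0, x0) * (1 - fx) * (1 - fy) +
                  img(y0, x1) * fx       * (1 - fy) +
                  img(y1, x0) * (1 - fx) * fy +
                  img(y1, x1) * fx       * fy;
    }
  }
  return out;
}

// Accumulate Gaussian-profile blobs onto an image. cx, cy are 0-based
// continuous centre coordinates (column, row); each blob is rendered on a
// local patch of half-width `cut` standard deviations.
// [[Rcpp::export]]
arma::mat cpp_add_blobs(arma::mat img, const arma::vec& cx, const arma::vec& cy,
                        const arma::vec& amp, double sigma, double cut) {
  const int nr = img.n_rows, nc = img.n_cols;
  const double r = cut * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (arma::uword p = 0; p < cx.n_elem; ++p) {
    int i0 = std::max(0, (int)std::floor(cy(p) - r));
    int i1 = std::min(nr - 1, (int)std::ceil(cy(p) + r));
    int j0 = std::max(0, (int)std::floor(cx(p) - r));
    int j1 = std::min(nc - 1, (int)std::ceil(cx(p) + r));
    if (i0 > i1 || j0 > j1) continue;
    for (int j = j0; j <= j1; ++j) {
      double dx2 = (j - cx(p)) * (j - cx(p));
      for (int i = i0; i <= i1; ++i) {
        double d2 = dx2 + (i - cy(p)) * (i - cy(p));
        img(i, j) += amp(p) * std::exp(-d2 * inv2s2);
      }
    }
  }
  return img;
}
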