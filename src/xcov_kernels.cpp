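// Numeric kernels for the XCOV pipeline: columnwise zero-phase IIR filtering
// and FFT-based pairwise normalized cross-correlation. Kept free of analysis
// logic (match-filter decisions, aggregation, peak picking live in R).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Direct-form II transposed single-pass IIR filter, zero initial state.
static vec iir_filter(const vec& b, const vec& a, const vec& x) {
  const uword nb = b.n_elem, na = a.n_elem;
  const uword nz = std::max(nb, na) - 1;
  vec z = zeros<vec>(nz + 1);  // one spare to simplify indexing
  vec y(x.n_elem);
  for (uword t = 0; t < x.n_elem; ++t) {
    double xt = x(t);
    double yt = b(0) * xt + z(0);
    for (uword k = 1; k <= nz; ++k) {
      double bk = (k < nb) ? b(k) : 0.0;
      double ak = (k < na) ? a(k) : 0.0;
      z(k - 1) = bk * xt - ak * yt + z(k);
    }
    y(t) = yt;
  }
  return y;
}

// Forward-backward (zero-phase) filtering of each column of x.
// Columns are padded on both ends with odd-reflected extensions of length
// `pad` to suppress edge transients, filtered, time-reversed, filtered again,
// and trimmed. Coefficients must describe a stable filter with a(0) == 1.
// [[Rcpp::export]]
arma::mat cpp_filtfilt(const arma::vec& b, const arma::vec& a,
                       const arma::mat& x, int pad) {
  const uword n = x.n_rows, m = x.n_cols;
  if (n < 2) Rcpp::stop("signals must have at least 2 samples");
  uword p = (uword)std::min<int>(std::max(pad, 0), (int)n - 1);
  mat out(n, m);
  for (uword j = 0; j < m; ++j) {
    vec xj = x.col(j);
    vec ext(n + 2 * p);
    // odd reflection: 2*x[0] - x[p..1], x, 2*x[n-1] - x[n-2..n-1-p]
    for (uword k = 0; k < p; ++k) ext(k) = 2.0 * xj(0) - xj(p - k);
    ext.subvec(p, p + n - 1) = xj;
    for (uword k = 0; k < p; ++k) ext(p + n + k) = 2.0 * xj(n - 1) - xj(n - 2 - k);
    vec y = iir_filter(b, a, ext);
    y = reverse(y);
    y = iir_filter(b, a, y);
    y = reverse(y);
    out.col(j) = y.subvec(p, p + n - 1);
  }
  return out;
}

// All pairwise normalized cross-correlations of the columns of x.
// For the p-th unordered pair (i, j), i < j (column-major enumeration:
// (1,2), (1,3), (2,3), ...), column p of the result holds
//   c_{ij}(l) = sum_t x_i[t + l] * x_j[t] / sqrt(E_i * E_j)
// for integer lags l = -lmax..lmax (rows), with E the signal energies.
// Pairs with a zero-energy member are returned as all-zero columns; the
// energies vector lets the caller disqualify them.
// [[Rcpp::export]]
Rcpp::List cpp_pairwise_xcov(const arma::mat& x, int lmax) {
  const uword n = x.n_rows, m = x.n_cols;
  if (m < 2) Rcpp::stop("need at least 2 trials");
  if (lmax < 1 || (uword)lmax >= n) Rcpp::stop("lmax out of range");
  // nfft >= n + lmax keeps circular wrap-around out of |lag| <= lmax
  uword nfft = 1;
  while (nfft < n + (uword)lmax) nfft <<= 1;

  cx_mat F(nfft, m);
  vec energy(m);
  for (uword j = 0; j < m; ++j) {
    vec xp = zeros<vec>(nfft);
    xp.head(n) = x.col(j);
    F.col(j) = fft(xp);
    energy(j) = dot(x.col(j), x.col(j));
  }

  const uword npairs = m * (m - 1) / 2;
  const uword nlag = 2 * (uword)lmax + 1;
  mat cc(nlag, npairs);
  umat pairs(2, npairs);
  {
    uword p = 0;
    for (uword i = 0; i + 1 < m; ++i)
      for (uword j = i + 1; j < m; ++j, ++p) { pairs(0, p) = i; pairs(1, p) = j; }
  }
  // cross-spectra of real signals have real cross-correlations, so two
  // pairs can share one complex inverse FFT (one in Re, one in Im)
  for (uword p = 0; p < npairs; p += 2) {
    const bool two = (p + 1 < npairs);
    cx_vec prod = F.col(pairs(0, p)) % conj(F.col(pairs(1, p)));
    if (two) {
      prod += cx_double(0.0, 1.0) *
        (F.col(pairs(0, p + 1)) % conj(F.col(pairs(1, p + 1))));
    }
    cx_vec full = ifft(prod);
    for (uword q = p; q < p + (two ? 2u : 1u); ++q) {
      double denom = std::sqrt(energy(pairs(0, q)) * energy(pairs(1, q)));
      if (denom <= 0.0) { cc.col(q).zeros(); continue; }
      // full[l] = sum_t x_i[t+l] x_j[t] for l >= 0; negative lags wrap
      for (int l = -lmax; l <= lmax; ++l) {
        uword idx = (l >= 0) ? (uword)l : nfft + l;
        double v = (q == p) ? full(idx).real() : full(idx).imag();
        cc((uword)(l + lmax), q) = v / denom;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("cc") = cc,
                            Rcpp::Named("energy") = energy);
}
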