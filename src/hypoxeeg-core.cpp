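#include <Rcpp.h>
using namespace Rcpp;

// Accumulate imaginary cross-spectrum sums for one epoch.
// are, aim: real/imaginary tapered spectra, dim (n_bins, n_ch, n_tapers).
// Returns sum over tapers of Im(S_ij) and |Im(S_ij)| per (bin, i, j), with
// Im(x_i * conj(x_j)) = Im(x_i) Re(x_j) - Re(x_i) Im(x_j).
// [[Rcpp::export]]
List wpli_epoch_sums(NumericVector are, NumericVector aim,
                     int n_bins, int n_ch, int n_tapers) {
  NumericVector sum_im(static_cast<R_xlen_t>(n_bins) * n_ch * n_ch);
  NumericVector sum_abs(static_cast<R_xlen_t>(n_bins) * n_ch * n_ch);
  const double *A = are.begin();
  const double *B = aim.begin();
  double *SI = sum_im.begin();
  double *SA = sum_abs.begin();
  const R_xlen_t plane = static_cast<R_xlen_t>(n_bins) * n_ch;
  for (int k = 0; k < n_tapers; ++k) {
    const double *Ak = A + k * plane;
    const double *Bk = B + k * plane;
    for (int j = 0; j < n_ch; ++j) {
      const double *Aj = Ak + static_cast<R_xlen_t>(j) * n_bins;
      const double *Bj = Bk + static_cast<R_xlen_t>(j) * n_bins;
      double *si = SI + static_cast<R_xlen_t>(j) * plane;
      double *sa = SA + static_cast<R_xlen_t>(j) * plane;
      for (int i = 0; i < n_ch; ++i) {
        const double *Ai = Ak + static_cast<R_xlen_t>(i) * n_bins;
        const double *Bi = Bk + static_cast<R_xlen_t>(i) * n_bins;
        double *sij = si + static_cast<R_xlen_t>(i) * n_bins;
        double *saj = sa + static_cast<R_xlen_t>(i) * n_bins;
        for (int b = 0; b < n_bins; ++b) {
          const double v = Bi[b] * Aj[b] - Ai[b] * Bj[b];
          sij[b] += v;
          saj[b] += std::fabs(v);
        }
      }
    }
  }
  sum_im.attr("dim") = IntegerVector::create(n_bins, n_ch, n_ch);
  sum_abs.attr("dim") = IntegerVector::create(n_bins, n_ch, n_ch);
  return List::create(Named("im") = sum_im, Named("abs") = sum_abs);
}

// Causal IIR filtering (direct form II transposed), column-wise over a
// time x channel matrix. Coefficients must be normalized so a[0] = 1.
// [[Rcpp::export]]
NumericMatrix iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericMatrix x) {
  const int n = x.nrow();
  const int m = x.ncol();
  const int nw = std::max(b.size(), a.size());
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0);
  std::copy(b.begin(), b.end(), bb.begin());
  std::copy(a.begin(), a.end(), aa.begin());
  NumericMatrix y(n, m);
  std::vector<double> w(nw, 0.0);
  const double b0 = bb[0];
  for (int c = 0; c < m; ++c) {
    std::fill(w.begin(), w.end(), 0.0);
    const double *xc = &x(0, c);
    double *yc = &y(0, c);
    for (int t = 0; t < n; ++t) {
      const double xt = xc[t];
      const double yt = b0 * xt + w[0];
      for (int s = 1; s < nw; ++s) {
        w[s - 1] = bb[s] * xt - aa[s] * yt + w[s];
      }
      yc[t] = yt;
    }
  }
  return y;
}
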