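#include <Rcpp.h>
using namespace Rcpp;

// Causal direct-form-I IIR pass over one buffer, in place.
// History before the buffer start: x = x[0] (constant), y = 0. For a
// bandpass (sum(b) == 0) this equals the steady state of a constant
// prehistory.
static void iir_pass(std::vector<double>& x, const NumericVector& b,
                     const NumericVector& a) {
  const int n = x.size(), nb = b.size(), na = a.size();
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb; ++j) {
      acc += b[j] * (i - j >= 0 ? x[i - j] : x[0]);
    }
    for (int j = 1; j < na; ++j) {
      if (i - j >= 0) acc -= a[j] * y[i - j];
    }
    y[i] = acc;
  }
  x.swap(y);
}

// Zero-phase filtering of each column of x: odd-extension padding of
// length padlen at both ends, forward pass, backward pass, trim.
// [[Rcpp::export]]
NumericMatrix filtfilt_cpp(NumericMatrix x, NumericVector b,
                           NumericVector a, int padlen) {
  const int n = x.nrow(), k = x.ncol();
  const int L = std::min(padlen, n - 1);
  NumericMatrix out(n, k);
  std::vector<double> buf(n + 2 * L);
  for (int c = 0; c < k; ++c) {
    NumericMatrix::Column col = x(_, c);
    for (int i = 0; i < L; ++i) buf[i] = 2.0 * col[0] - col[L - i];
    for (int i = 0; i < n; ++i) buf[L + i] = col[i];
    for (int i = 0; i < L; ++i) {
      buf[L + n + i] = 2.0 * col[n - 1] - col[n - 2 - i];
    }
    iir_pass(buf, b, a);
    std::reverse(buf.begin(), buf.end());
    iir_pass(buf, b, a);
    std::reverse(buf.begin(), buf.end());
    for (int i = 0; i < n; ++i) out(i, c) = buf[L + i];
  }
  return out;
}
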