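#include <Rcpp.h>
using namespace Rcpp;

// Stateful IIR filtering (direct form II transposed). a[0] must be nonzero;
// coefficients are normalized by a[0]. `zi` carries the n-1 delay states so a
// stream processed block-wise equals the whole-stream result exactly.
// [[Rcpp::export]]
List iir_filter_state(NumericVector b, NumericVector a, NumericVector x,
                      Nullable<NumericVector> zi = R_NilValue) {
  int nb = b.size(), na = a.size();
  int n = std::max(na, nb);
  if (n < 1) stop("empty filter coefficients");
  double a0 = a[0];
  if (a0 == 0.0) stop("a[0] must be nonzero");
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; i++) bb[i] = b[i] / a0;
  for (int i = 0; i < na; i++) aa[i] = a[i] / a0;
  std::vector<double> z(n > 1 ? n - 1 : 1, 0.0);
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    if ((int)z0.size() != n - 1) stop("zi must have length n-1");
    for (int i = 0; i < n - 1; i++) z[i] = z0[i];
  }
  int N = x.size();
  NumericVector y(N);
  for (int t = 0; t < N; t++) {
    double xt = x[t];
    double yt = bb[0] * xt + (n > 1 ? z[0] : 0.0);
    for (int i = 0; i < n - 2; i++) z[i] = z[i + 1] + bb[i + 1] * xt - aa[i + 1] * yt;
    if (n > 1) z[n - 2] = bb[n - 1] * xt - aa[n - 1] * yt;
    y[t] = yt;
  }
  NumericVector zf(n > 1 ? n - 1 : 0);
  for (int i = 0; i < n - 1; i++) zf[i] = z[i];
  return List::create(_["y"] = y, _["zf"] = zf);
}

// Causal rectangular moving average of fixed width with carried state.
// Pre-history is treated as zeros (warm-up); `state` is the ring buffer of the
// last `width` inputs plus the running sum, so block-wise equals whole-stream.
// [[Rcpp::export]]
List moving_average_state(NumericVector x, int width,
                          Nullable<List> state = R_NilValue) {
  if (width < 1) stop("width must be >= 1");
  std::vector<double> buf(width, 0.0);
  int idx = 0;
  double sum = 0.0;
  if (state.isNotNull()) {
    List st(state);
    NumericVector b0 = st["buf"];
    if ((int)b0.size() != width) stop("state width mismatch");
    for (int i = 0; i < width; i++) buf[i] = b0[i];
    idx = as<int>(st["idx"]);
    sum = as<double>(st["sum"]);
  }
  int N = x.size();
  NumericVector y(N);
  for (int t = 0; t < N; t++) {
    sum += x[t] - buf[idx];
    buf[idx] = x[t];
    idx = (idx + 1) % width;
    y[t] = sum / width;
  }
  NumericVector bf(width);
  for (int i = 0; i < width; i++) bf[i] = buf[i];
  return List::create(_["y"] = y,
                      _["state"] = List::create(_["buf"] = bf, _["idx"] = idx,
                                                _["sum"] = sum));
}
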