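#include <Rcpp.h>
using namespace Rcpp;

// Recursive-least-squares cancellation of a reference signal from a
// desired signal. Returns the a-priori error d[t] - w'u[t], i.e. the
// signal with the adaptively fitted reference contribution removed.
// u[t] is the tap vector (ref[t], ref[t-1], ..., ref[t-M+1]).
// [[Rcpp::export(name = "rls_cancel")]]
NumericVector rls_cancel(NumericVector d, NumericVector ref,
                         double lambda, int order, double delta = 100.0) {
  int n = d.size();
  if (ref.size() != n) stop("reference length must match signal length");
  if (order < 1) stop("order must be >= 1");
  int M = order;
  std::vector<double> w(M, 0.0), u(M, 0.0), k(M), Pu(M);
  std::vector<double> P(M * M, 0.0);
  for (int i = 0; i < M; i++) P[i * M + i] = delta;
  NumericVector out(n);
  for (int t = 0; t < n; t++) {
    for (int j = M - 1; j > 0; j--) u[j] = u[j - 1];
    u[0] = ref[t];
    double denom = lambda;
    for (int i = 0; i < M; i++) {
      double s = 0.0;
      for (int j = 0; j < M; j++) s += P[i * M + j] * u[j];
      Pu[i] = s;
      denom += u[i] * s;
    }
    for (int i = 0; i < M; i++) k[i] = Pu[i] / denom;
    double yhat = 0.0;
    for (int i = 0; i < M; i++) yhat += w[i] * u[i];
    double e = d[t] - yhat;
    out[t] = e;
    for (int i = 0; i < M; i++) w[i] += k[i] * e;
    // P = (P - k * u' * P) / lambda ; u'P == Pu' by symmetry
    for (int i = 0; i < M; i++)
      for (int j = 0; j < M; j++)
        P[i * M + j] = (P[i * M + j] - k[i] * Pu[j]) / lambda;
  }
  return out;
}
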