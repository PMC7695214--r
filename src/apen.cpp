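#include <Rcpp.h>
using namespace Rcpp;

// Mean pattern-match fraction for approximate entropy:
// mean over i of (#{ j : ||P(i) - P(j)|| < r }) / (n - m + 1),
// with P(i) = x[i : i+m-1]. Chebyshev (max) or Euclidean window distance;
// self-matches optionally included.
// [[Rcpp::export(name = "apen_component_cpp")]]
double apen_component_cpp(NumericVector x, int m, double r,
                          bool self_matches = true, bool chebyshev = true) {
  int n = x.size();
  if (m >= n) stop("pattern length m (%d) must be below sequence length (%d)", m, n);
  if (r <= 0) stop("similarity threshold r must be positive");
  int nw = n - m + 1;
  // integer match counts summed exactly; one final division keeps the
  // result bit-identical to a literal double-loop enumeration
  double total = self_matches ? (double) nw : 0.0;
  double r2 = r * r;
  for (int i = 0; i < nw; i++) {
    for (int j = i + 1; j < nw; j++) {
      bool match;
      if (chebyshev) {
        match = true;
        for (int k = 0; k < m; k++) {
          double dlt = x[i + k] - x[j + k];
          if (dlt < 0) dlt = -dlt;
          if (dlt >= r) { match = false; break; }
        }
      } else {
        double ss = 0.0;
        for (int k = 0; k < m; k++) {
          double dlt = x[i + k] - x[j + k];
          ss += dlt * dlt;
          if (ss >= r2) break;
        }
        match = ss < r2;
      }
      if (match) total += 2.0;
    }
  }
  return total / ((double) nw * (double) nw);
}
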