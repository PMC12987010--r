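#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy by direct template matching (Chebyshev distance, tolerance
// r, embedding dimension m). Counts unordered template pairs i < j whose
// m-length (B) and (m+1)-length (A) embeddings both stay within r; self
// matches are excluded by construction. Returns -log(A/B); 0 when B == 0
// (degenerate series), NA when A == 0 with B > 0 (no recurrence at m+1).
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  long long A = 0, B = 0;
  int nm = n - m; // number of (m+1)-length templates is nm - ... handled below
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (B == 0) return 0.0;
  if (A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}
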