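#include <Rcpp.h>
using namespace Rcpp;

// Pairwise template-match counts for sample entropy under the Chebyshev
// distance, with early abort on the first coordinate exceeding r.
//
// Returns unordered pair counts:
//   [0] matches of length-m templates over i = 1..N-m+1 (all m-templates)
//   [1] matches of length-m templates restricted to i = 1..N-m
//   [2] matches of length-(m+1) templates (i = 1..N-m)
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int n_tpl = n - m + 1;   // number of m-templates
  double sm_full = 0.0, sm_restr = 0.0, sm1 = 0.0;
  for (int i = 0; i < n_tpl - 1; ++i) {
    for (int j = i + 1; j < n_tpl; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      sm_full += 1.0;
      if (j < n_tpl - 1) {       // both (m+1)-templates exist
        sm_restr += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) sm1 += 1.0;
      }
    }
  }
  return NumericVector::create(sm_full, sm_restr, sm1);
}
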