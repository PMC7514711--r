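#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise template-match counting for sample entropy.
//
// For every unordered pair (i, j), i != j, of starting positions, the
// Chebyshev distance of the two length-L templates is the running maximum of
// |x[i+k] - x[j+k]| over k = 0..L-1.  A single sweep over pairs therefore
// yields the match counts for all template lengths 1..Lmax and all
// tolerances at once; tolerances must be sorted ascending so the inner loop
// can stop at the first tolerance that fails.  Counts are returned as doubles
// (pair counts can exceed 2^31 for long signals).

// [[Rcpp::export]]
NumericMatrix cpp_count_multi(NumericVector x, int Lmax, NumericVector R,
                              bool strict) {
  const int N = x.size();
  const int nt = R.size();
  if (Lmax < 1) stop("Lmax must be >= 1");
  for (int t = 1; t < nt; ++t)
    if (R[t] < R[t - 1]) stop("tolerances must be sorted ascending");
  NumericMatrix cnt(Lmax, nt);
  if (nt == 0 || N < 2) return cnt;
  const double Rmax = R[nt - 1];
  const double *px = REAL(x);
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      // a length-L template starting at j is valid iff j + L <= N
      const int kmax = std::min(Lmax, N - j);
      for (int k = 0; k < kmax; ++k) {
        const double diff = std::fabs(px[i + k] - px[j + k]);
        if (diff > d) d = diff;
        if (strict ? (d >= Rmax) : (d > Rmax)) break;
        // descending tolerances: once the distance fails one tolerance it
        // fails every smaller (stricter) one as well
        for (int t = nt - 1; t >= 0; --t) {
          if (strict ? (d < R[t]) : (d <= R[t]))
            cnt(k, t) += 1.0;
          else
            break;
        }
      }
    }
  }
  return cnt;
}
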