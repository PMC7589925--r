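#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window duplex scores of one miRNA along one transcript.
//
// mirna, tx: sequences coded 1..4 over the RNA alphabet (A,C,G,U).
// penalty: 4x4 base-pair penalty, indexed [miRNA base, target base].
// weight: per-miRNA-position multiplier (core positions doubled).
//
// miRNA position 1 (5' end) pairs the last base of each window, so the
// score of the window starting at s is
//   sum_i weight[i] * penalty(mirna[i], tx[s + L - 1 - i]).
// [[Rcpp::export]]
NumericVector scan_duplex_scores(IntegerVector mirna, IntegerVector tx,
                                 NumericMatrix penalty, NumericVector weight) {
  const int L = mirna.size();
  const int n = tx.size();
  const int W = n - L + 1;
  if (L == 0 || W < 1) return NumericVector(0);
  if (weight.size() != L) stop("weight length must equal miRNA length");
  NumericVector out(W);
  for (int s = 0; s < W; ++s) {
    double sc = 0.0;
    for (int i = 0; i < L; ++i) {
      sc += weight[i] * penalty(mirna[i] - 1, tx[s + L - 1 - i] - 1);
    }
    out[s] = sc;
  }
  return out;
}
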