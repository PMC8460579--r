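#include <Rcpp.h>
using namespace Rcpp;

// Optimal non-crossing one-to-one matching of two sorted fixation streams,
// maximising total temporal overlap. Only strictly positive overlaps may be
// matched. Among matchings of equal total overlap the backtrack prefers to
// leave the *latest* right fixation unmatched, i.e. ties are broken toward
// pairing with the earlier right fixation.
//
// Times are integer milliseconds in practice, so the DP scores (sums of
// overlaps) are exact in double precision and equality tests are safe.

// [[Rcpp::export]]
IntegerMatrix pair_dp_cpp(NumericVector ls, NumericVector le,
                          NumericVector rs, NumericVector re) {
  const int n = ls.size(), m = rs.size();
  NumericMatrix best(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double w = std::min(le[i - 1], re[j - 1]) -
                 std::max(ls[i - 1], rs[j - 1]);
      double b = std::max(best(i - 1, j), best(i, j - 1));
      if (w > 0) b = std::max(b, best(i - 1, j - 1) + w);
      best(i, j) = b;
    }
  }
  std::vector<int> li, rj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    if (best(i, j) == best(i, j - 1)) {
      --j;
    } else {
      double w = std::min(le[i - 1], re[j - 1]) -
                 std::max(ls[i - 1], rs[j - 1]);
      if (w > 0 && best(i, j) == best(i - 1, j - 1) + w) {
        li.push_back(i);
        rj.push_back(j);
        --i; --j;
      } else {
        --i;
      }
    }
  }
  const int k = li.size();
  IntegerMatrix out(k, 2);
  for (int t = 0; t < k; ++t) {
    out(t, 0) = li[k - 1 - t];
    out(t, 1) = rj[k - 1 - t];
  }
  colnames(out) = CharacterVector::create("left", "right");
  return out;
}
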