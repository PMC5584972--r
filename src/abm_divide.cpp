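#include <Rcpp.h>
using namespace Rcpp;

// Sequential division pass over ready cells (already shuffled by the
// caller). Each ready cell picks a uniformly random empty neighbour site
// for its daughter; with no empty neighbour the division is deferred and
// the accumulator stays capped at 1. Uses R's RNG so runs are reproducible
// from set.seed(). Matrices are modified in place; the R wrapper passes
// fresh copies.
// [[Rcpp::export]]
int divide_ready_cpp(IntegerMatrix strain, NumericMatrix acc,
                     IntegerVector ready_r, IntegerVector ready_c,
                     IntegerVector off_r, IntegerVector off_c) {
  const int nr = strain.nrow(), nc = strain.ncol();
  const int nofs = off_r.size();
  int divisions = 0;
  std::vector<int> er(nofs), ec(nofs);
  for (int i = 0; i < ready_r.size(); ++i) {
    const int r = ready_r[i] - 1, c = ready_c[i] - 1;
    if (acc(r, c) < 1.0 || strain(r, c) == 0) continue;
    int nempty = 0;
    for (int j = 0; j < nofs; ++j) {
      const int rr = r + off_r[j], cc = c + off_c[j];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && strain(rr, cc) == 0) {
        er[nempty] = rr; ec[nempty] = cc; ++nempty;
      }
    }
    if (nempty == 0) {
      acc(r, c) = 1.0;  // deferred: cap the accumulator
      continue;
    }
    int pick = (int)(unif_rand() * nempty);
    if (pick == nempty) pick = nempty - 1;  // guard unif_rand() == 1.0
    strain(er[pick], ec[pick]) = strain(r, c);
    acc(er[pick], ec[pick]) = 0.0;
    acc(r, c) -= 1.0;  // carry the remainder so the mean rate is preserved
    ++divisions;
  }
  return divisions;
}
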