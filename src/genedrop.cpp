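#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One gamete from the parent haplotypes in rows h1/h2 of H, written to row
// `orow` of `out`.  Crossovers are Poisson along each chromosome (Haldane,
// no interference); map positions are chromosome-local Morgans.
static void make_gamete(const IntegerMatrix &H, int h1, int h2,
                        const NumericVector &pos, const IntegerVector &chr_first,
                        const IntegerVector &chr_last, const NumericVector &chr_len,
                        IntegerMatrix &out, int orow) {
  const int nchr = chr_first.size();
  std::vector<double> xo;
  for (int c = 0; c < nchr; ++c) {
    const int a = chr_first[c], b = chr_last[c]; // inclusive, 0-based
    const double L = chr_len[c];
    const int nxo = (int)R::rpois(L);
    xo.clear();
    xo.reserve(nxo);
    for (int j = 0; j < nxo; ++j) xo.push_back(R::runif(0.0, L));
    std::sort(xo.begin(), xo.end());
    int cur = (R::unif_rand() < 0.5) ? 0 : 1; // independent start per chromosome
    size_t xi = 0;
    for (int k = a; k <= b; ++k) {
      while (xi < xo.size() && xo[xi] < pos[k]) {
        cur = 1 - cur;
        ++xi;
      }
      out(orow, k) = (cur == 0) ? H(h1, k) : H(h2, k);
    }
  }
}

// Drop one discrete generation: offspring i receives one recombinant gamete
// from parent sire[i] and one from dam[i] (0-based indices into the parent
// generation; parent j owns haplotype rows 2j and 2j+1 of H).
// [[Rcpp::export]]
IntegerMatrix drop_generation_cpp(IntegerMatrix H, IntegerVector sire, IntegerVector dam,
                                  NumericVector pos, IntegerVector chr_first,
                                  IntegerVector chr_last, NumericVector chr_len) {
  const int n = sire.size();
  const int m = H.ncol();
  IntegerMatrix out(2 * n, m);
  for (int i = 0; i < n; ++i) {
    make_gamete(H, 2 * sire[i], 2 * sire[i] + 1, pos, chr_first, chr_last, chr_len,
                out, 2 * i);
    make_gamete(H, 2 * dam[i], 2 * dam[i] + 1, pos, chr_first, chr_last, chr_len,
                out, 2 * i + 1);
  }
  return out;
}
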