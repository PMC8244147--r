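#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation with crossover recombination.
//
// H: haplotype matrix, 2 rows per individual (rows 2p-1, 2p for individual
// p, 1-based), loci in columns sorted by chromosome then map position.
// parent: 1-based individual index in H contributing each gamete.
// chr_id: 1-based chromosome of each locus; pos: map position in Morgan
// within its chromosome; chr_len: chromosome length in Morgan.
//
// Per gamete and chromosome: crossover count ~ Poisson(chr_len), crossover
// positions uniform, starting haplotype a fair coin; no interference. Uses
// R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix make_gametes_cpp(const IntegerMatrix& H,
                               const IntegerVector& parent,
                               const IntegerVector& chr_id,
                               const NumericVector& pos,
                               double chr_len) {
  const int m = H.ncol();
  const int ng = parent.size();
  if (chr_id.size() != m || pos.size() != m)
    stop("chr_id/pos length must match the number of loci");
  int n_chr = 0;
  for (int j = 0; j < m; ++j) n_chr = std::max(n_chr, chr_id[j]);
  std::vector<int> cstart(n_chr + 1, m);
  for (int j = m - 1; j >= 0; --j) cstart[chr_id[j] - 1] = j;
  for (int c = n_chr - 1; c >= 0; --c)
    if (cstart[c] == m && cstart[c + 1] < m) cstart[c] = cstart[c + 1];

  IntegerMatrix out(ng, m);
  std::vector<double> xo;
  for (int g = 0; g < ng; ++g) {
    const int p = parent[g] - 1;
    if (p < 0 || 2 * p + 1 >= H.nrow()) stop("parent index out of range");
    for (int c = 0; c < n_chr; ++c) {
      const int lo = cstart[c], hi = cstart[c + 1];
      if (lo >= hi) continue;
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      const int nxo = (int) R::rpois(chr_len);
      if (nxo == 0) {
        for (int j = lo; j < hi; ++j) out(g, j) = H(2 * p + cur, j);
      } else {
        xo.assign(nxo, 0.0);
        for (int t = 0; t < nxo; ++t) xo[t] = unif_rand() * chr_len;
        std::sort(xo.begin(), xo.end());
        int t = 0;
        for (int j = lo; j < hi; ++j) {
          while (t < nxo && xo[t] < pos[j]) { cur = 1 - cur; ++t; }
          out(g, j) = H(2 * p + cur, j);
        }
      }
    }
  }
  return out;
}
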