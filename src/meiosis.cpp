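#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch gamete formation. `haplo` holds two rows per individual; `parent_row`
// gives the 1-based index of each parent's FIRST haplotype row, one entry per
// gamete requested. Crossover counts are Poisson(chr_len in Morgans) per
// chromosome, breakpoint positions uniform, starting strand random, strands
// alternate at breakpoints. Mutation flips alleles symmetrically.
//
// Uses R's RNG throughout so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& haplo,
                               const IntegerVector& parent_row,
                               const NumericVector& pos,
                               const IntegerVector& chr_first,
                               const IntegerVector& chr_last,
                               const NumericVector& chr_len,
                               double mut_rate) {
  const int n_gam = parent_row.size();
  const int L = haplo.ncol();
  const int n_chr = chr_first.size();
  IntegerMatrix out(n_gam, L);
  std::vector<double> bp;
  bp.reserve(16);

  for (int g = 0; g < n_gam; ++g) {
    const int prow = parent_row[g] - 1;
    for (int c = 0; c < n_chr; ++c) {
      const int lo = chr_first[c] - 1;
      const int hi = chr_last[c] - 1;
      const int nx = (int) R::rpois(chr_len[c]);
      bp.clear();
      for (int k = 0; k < nx; ++k) bp.push_back(unif_rand() * chr_len[c]);
      std::sort(bp.begin(), bp.end());
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      size_t bi = 0;
      for (int l = lo; l <= hi; ++l) {
        while (bi < bp.size() && bp[bi] <= pos[l]) { strand ^= 1; ++bi; }
        out(g, l) = haplo(prow + strand, l);
      }
    }
    if (mut_rate > 0) {
      if (mut_rate >= 0.01) {
        // exact per-locus Bernoulli; only used for artificially high rates
        for (int l = 0; l < L; ++l)
          if (unif_rand() < mut_rate) out(g, l) ^= 1;
      } else {
        // draw the mutation count, then hit random loci; at realistic rates
        // (1e-5) repeat hits are vanishingly rare
        const int nm = (int) R::rbinom((double) L, mut_rate);
        for (int k = 0; k < nm; ++k) {
          int l = (int) (unif_rand() * L);
          if (l >= L) l = L - 1;
          out(g, l) ^= 1;
        }
      }
    }
  }
  return out;
}
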