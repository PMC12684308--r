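#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation with crossover mosaics.
//
// h1, h2: parental haplotypes (individuals x loci, 0/1 derived-allele codes).
// parent: 1-based row index of the parent contributing each gamete.
// gpos:   cumulative genetic position of each locus within its arm (Morgans).
// arm:    1-based arm index per locus; loci of one arm are contiguous and
//         sorted by gpos.
// arm_len: genetic length of each arm in Morgans.
//
// Arms assort freely (random starting phase per arm); crossover counts per
// arm are Poisson(arm_len) with breakpoints uniform on genetic distance.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix make_gametes_cpp(const IntegerMatrix& h1, const IntegerMatrix& h2,
                               const IntegerVector& parent,
                               const NumericVector& gpos,
                               const IntegerVector& arm,
                               const NumericVector& arm_len) {
  const int L = gpos.size();
  const int G = parent.size();
  const int n_arms = arm_len.size();
  IntegerMatrix out(G, L);

  std::vector<int> a_start(n_arms, -1), a_end(n_arms, -1);
  for (int l = 0; l < L; ++l) {
    int a = arm[l] - 1;
    if (a_start[a] < 0) a_start[a] = l;
    a_end[a] = l;
  }

  std::vector<double> bp;
  for (int g = 0; g < G; ++g) {
    const int p = parent[g] - 1;
    for (int a = 0; a < n_arms; ++a) {
      if (a_start[a] < 0) continue;
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int nco = (int) R::rpois(arm_len[a]);
      bp.resize(nco);
      for (int k = 0; k < nco; ++k) bp[k] = unif_rand() * arm_len[a];
      std::sort(bp.begin(), bp.end());
      int k = 0;
      for (int l = a_start[a]; l <= a_end[a]; ++l) {
        while (k < nco && bp[k] < gpos[l]) { phase ^= 1; ++k; }
        out(g, l) = phase ? h2(p, l) : h1(p, l);
      }
    }
  }
  return out;
}

// Multiplicative log fitness over diploid dosages.
// log w = sum over heterozygous loci of log_het + homozygous-derived of log_hom.
// [[Rcpp::export]]
NumericVector log_fitness_cpp(const IntegerMatrix& h1, const IntegerMatrix& h2,
                              const NumericVector& log_het,
                              const NumericVector& log_hom) {
  const int N = h1.nrow(), L = h1.ncol();
  NumericVector out(N);
  for (int l = 0; l < L; ++l) {
    const double lhet = log_het[l], lhom = log_hom[l];
    if (lhet == 0.0 && lhom == 0.0) continue;
    for (int i = 0; i < N; ++i) {
      const int d = h1(i, l) + h2(i, l);
      if (d == 1) out[i] += lhet;
      else if (d == 2) out[i] += lhom;
    }
  }
  return out;
}
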