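#include <Rcpp.h>
using namespace Rcpp;

// Clean-split two-population coalescent: each population starts with n
// sampled gene copies and coalesces independently for tau units of the
// locus's coalescent timescale; surviving lineages then merge into the
// ancestral population. The two samples are reciprocally monophyletic
// iff the first between-population coalescence happens when each side
// has already collapsed to a single ancestral lineage.

static int lineages_at(double tau, int n) {
  double t = 0.0;
  int k = n;
  while (k > 1) {
    t += R::exp_rand() / (k * (k - 1) / 2.0);
    if (t > tau) break;
    --k;
  }
  return k;
}

// [[Rcpp::export]]
int recip_mono_cpp(double tau, int n, int n_loci, int reps) {
  int succ = 0;
  for (int r = 0; r < reps; ++r) {
    bool all_mono = true;
    for (int l = 0; l < n_loci && all_mono; ++l) {
      int a = lineages_at(tau, n);
      int b = lineages_at(tau, n);
      // ancestral phase: only lineage counts matter; a coalescence picks a
      // uniform pair, and any A-B join before state (1,1) breaks monophyly
      while (a + b > 2 || a != 1 || b != 1) {
        double tot = (a + b) * (a + b - 1) / 2.0;
        double pAA = a * (a - 1) / 2.0 / tot;
        double pBB = b * (b - 1) / 2.0 / tot;
        double u = unif_rand();
        if (u < pAA) --a;
        else if (u < pAA + pBB) --b;
        else { all_mono = false; break; }
      }
    }
    if (all_mono) ++succ;
  }
  return succ;
}
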