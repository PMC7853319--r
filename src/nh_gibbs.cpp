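#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the six-category hybrid-class model. Categories are
// genotype-frequency classes defined by phi = (P(both copies from A),
// P(one from each), P(both from B)). Parental allele frequencies get a
// Dirichlet(freq_prior) prior informed by designated pure reference
// individuals plus gene copies attributed to each species by the current
// category assignments. Category proportions pi are either fixed or sampled
// from a Dirichlet(1) posterior over the unknown individuals.
//
// With a handful of loci and alleles there are few distinct genotypes, so
// per-sweep likelihood components are cached per (locus, genotype) rather
// than recomputed per individual.
//
// Genotypes: U x 2L integer allele codes (1-based), NA = missing.

static void rdirichlet(const std::vector<double> &shape, std::vector<double> &out) {
  double tot = 0.0;
  const int n = shape.size();
  for (int j = 0; j < n; ++j) {
    double g = R::rgamma(shape[j], 1.0);
    if (g < 1e-300) g = 1e-300;
    out[j] = g;
    tot += g;
  }
  for (int j = 0; j < n; ++j) out[j] /= tot;
}

// [[Rcpp::export]]
List nh_gibbs_cpp(IntegerMatrix unk, IntegerMatrix refA, IntegerMatrix refB,
                  IntegerVector n_alleles, NumericMatrix phi,
                  int burnin, int sweeps, bool sample_pi,
                  NumericVector pi_fixed, double freq_prior) {
  const int U = unk.nrow();
  const int L = n_alleles.size();
  const int C = phi.nrow();
  if (unk.ncol() != 2 * L) stop("genotype matrix must have 2 columns per locus");

  // genotype-pair index per locus: (a1 <= a2) -> a1-1 + J*(a2-1) compacted
  std::vector<int> npair(L);
  std::vector<std::vector<int> > pair_a1(L), pair_a2(L);
  std::vector<std::vector<int> > pair_idx(L); // J*J lookup
  for (int l = 0; l < L; ++l) {
    const int J = n_alleles[l];
    pair_idx[l].assign(J * J, -1);
    int k = 0;
    for (int i = 0; i < J; ++i)
      for (int j = i; j < J; ++j) {
        pair_idx[l][i * J + j] = k;
        pair_a1[l].push_back(i);
        pair_a2[l].push_back(j);
        ++k;
      }
    npair[l] = k;
  }
  // per (individual, locus) genotype index, -1 = missing
  std::vector<int> gidx(U * L);
  for (int i = 0; i < U; ++i)
    for (int l = 0; l < L; ++l) {
      int a1 = unk(i, 2 * l), a2 = unk(i, 2 * l + 1);
      if (a1 == NA_INTEGER || a2 == NA_INTEGER) { gidx[i * L + l] = -1; continue; }
      int lo = std::min(a1, a2) - 1, hi = std::max(a1, a2) - 1;
      gidx[i * L + l] = pair_idx[l][lo * n_alleles[l] + hi];
    }

  // fixed reference allele counts per species
  std::vector<std::vector<double> > refCntA(L), refCntB(L);
  for (int l = 0; l < L; ++l) {
    refCntA[l].assign(n_alleles[l], 0.0);
    refCntB[l].assign(n_alleles[l], 0.0);
    for (int i = 0; i < refA.nrow(); ++i)
      for (int c = 0; c < 2; ++c) {
        int a = refA(i, 2 * l + c);
        if (a != NA_INTEGER) refCntA[l][a - 1] += 1.0;
      }
    for (int i = 0; i < refB.nrow(); ++i)
      for (int c = 0; c < 2; ++c) {
        int a = refB(i, 2 * l + c);
        if (a != NA_INTEGER) refCntB[l][a - 1] += 1.0;
      }
  }

  std::vector<std::vector<double> > pA(L), pB(L);
  std::vector<double> shape;
  for (int l = 0; l < L; ++l) {
    shape.assign(n_alleles[l], freq_prior);
    for (int j = 0; j < n_alleles[l]; ++j) shape[j] += refCntA[l][j];
    pA[l].assign(n_alleles[l], 0.0);
    rdirichlet(shape, pA[l]);
    shape.assign(n_alleles[l], freq_prior);
    for (int j = 0; j < n_alleles[l]; ++j) shape[j] += refCntB[l][j];
    pB[l].assign(n_alleles[l], 0.0);
    rdirichlet(shape, pB[l]);
  }

  std::vector<double> pi(C);
  for (int c = 0; c < C; ++c) pi[c] = sample_pi ? 1.0 / C : pi_fixed[c];

  std::vector<int> cat(U);
  for (int i = 0; i < U; ++i) cat[i] = (int)std::floor(unif_rand() * C);

  NumericMatrix post(U, C);
  std::vector<double> piSum(C, 0.0);
  std::vector<std::vector<double> > pASum(L), pBSum(L);
  for (int l = 0; l < L; ++l) {
    pASum[l].assign(n_alleles[l], 0.0);
    pBSum[l].assign(n_alleles[l], 0.0);
  }

  // per-sweep caches, indexed [locus][pair]
  std::vector<std::vector<double> > hwA(L), mix(L), hwB(L), wAfirst(L);
  std::vector<std::vector<double> > catlik(L); // [locus][pair*C + c]
  for (int l = 0; l < L; ++l) {
    hwA[l].resize(npair[l]);
    mix[l].resize(npair[l]);
    hwB[l].resize(npair[l]);
    wAfirst[l].resize(npair[l]);
    catlik[l].resize(npair[l] * C);
  }
  std::vector<double> pr(C), w(3);
  std::vector<std::vector<double> > cntA(L), cntB(L);
  const bool retain_scale = true;

  for (int it = 0; it < burnin + sweeps; ++it) {
    // refresh per-genotype caches from current frequencies
    for (int l = 0; l < L; ++l) {
      for (int k = 0; k < npair[l]; ++k) {
        int i = pair_a1[l][k], j = pair_a2[l][k];
        double a, m, b, wa;
        if (i == j) {
          a = pA[l][i] * pA[l][i];
          b = pB[l][i] * pB[l][i];
          m = pA[l][i] * pB[l][i];
          wa = 1.0; // homozygote: one copy to each species either way
        } else {
          a = 2.0 * pA[l][i] * pA[l][j];
          b = 2.0 * pB[l][i] * pB[l][j];
          double m1 = pA[l][i] * pB[l][j], m2 = pA[l][j] * pB[l][i];
          m = m1 + m2;
          wa = m > 0 ? m1 / m : 0.5; // P(first-listed allele is the A copy)
        }
        hwA[l][k] = a; mix[l][k] = m; hwB[l][k] = b; wAfirst[l][k] = wa;
        for (int c = 0; c < C; ++c)
          catlik[l][k * C + c] = phi(c, 0) * a + phi(c, 1) * m + phi(c, 2) * b;
      }
    }
    // category update given pi and frequencies (products of <= L bounded
    // likelihoods: no underflow risk at the panel sizes targeted here)
    for (int i = 0; i < U; ++i) {
      for (int c = 0; c < C; ++c) pr[c] = pi[c];
      for (int l = 0; l < L; ++l) {
        int k = gidx[i * L + l];
        if (k < 0) continue;
        const double *cl = &catlik[l][k * C];
        for (int c = 0; c < C; ++c) pr[c] *= cl[c];
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) tot += pr[c];
      int pick;
      if (tot <= 0.0) {
        pick = (int)std::floor(unif_rand() * C);
        if (it >= burnin && retain_scale)
          for (int c = 0; c < C; ++c) post(i, c) += 1.0 / C;
      } else {
        double u = unif_rand() * tot, acc = 0.0;
        pick = C - 1;
        for (int c = 0; c < C; ++c) {
          acc += pr[c];
          if (u <= acc) { pick = c; break; }
        }
        if (it >= burnin && retain_scale)
          for (int c = 0; c < C; ++c) post(i, c) += pr[c] / tot;
      }
      cat[i] = pick;
    }
    // attribute gene copies to species given categories, then update freqs
    for (int l = 0; l < L; ++l) {
      cntA[l] = refCntA[l];
      cntB[l] = refCntB[l];
    }
    for (int i = 0; i < U; ++i) {
      const int c = cat[i];
      for (int l = 0; l < L; ++l) {
        int k = gidx[i * L + l];
        if (k < 0) continue;
        w[0] = phi(c, 0) * hwA[l][k];
        w[1] = phi(c, 1) * mix[l][k];
        w[2] = phi(c, 2) * hwB[l][k];
        double tot = w[0] + w[1] + w[2];
        int origin;
        if (tot <= 0.0) origin = 1;
        else {
          double u = unif_rand() * tot;
          origin = (u <= w[0]) ? 0 : (u <= w[0] + w[1] ? 1 : 2);
        }
        int a1 = pair_a1[l][k], a2 = pair_a2[l][k];
        if (origin == 0) {
          cntA[l][a1] += 1.0;
          cntA[l][a2] += 1.0;
        } else if (origin == 2) {
          cntB[l][a1] += 1.0;
          cntB[l][a2] += 1.0;
        } else if (a1 == a2) {
          cntA[l][a1] += 1.0;
          cntB[l][a1] += 1.0;
        } else if (unif_rand() <= wAfirst[l][k]) {
          cntA[l][a1] += 1.0;
          cntB[l][a2] += 1.0;
        } else {
          cntA[l][a2] += 1.0;
          cntB[l][a1] += 1.0;
        }
      }
    }
    for (int l = 0; l < L; ++l) {
      shape.assign(n_alleles[l], freq_prior);
      for (int j = 0; j < n_alleles[l]; ++j) shape[j] += cntA[l][j];
      rdirichlet(shape, pA[l]);
      shape.assign(n_alleles[l], freq_prior);
      for (int j = 0; j < n_alleles[l]; ++j) shape[j] += cntB[l][j];
      rdirichlet(shape, pB[l]);
    }
    // mixing-proportion update
    if (sample_pi) {
      shape.assign(C, 1.0);
      for (int i = 0; i < U; ++i) shape[cat[i]] += 1.0;
      rdirichlet(shape, pi);
    }
    if (it >= burnin) {
      for (int c = 0; c < C; ++c) piSum[c] += pi[c];
      for (int l = 0; l < L; ++l)
        for (int j = 0; j < n_alleles[l]; ++j) {
          pASum[l][j] += pA[l][j];
          pBSum[l][j] += pB[l][j];
        }
    }
  }

  const double ns = (double)sweeps;
  for (int i = 0; i < U; ++i) {
    double rs = 0.0;
    for (int c = 0; c < C; ++c) rs += post(i, c);
    for (int c = 0; c < C; ++c) post(i, c) /= rs;
  }
  NumericVector piOut(C);
  for (int c = 0; c < C; ++c) piOut[c] = piSum[c] / ns;
  List pAOut(L), pBOut(L);
  for (int l = 0; l < L; ++l) {
    pAOut[l] = NumericVector(pASum[l].begin(), pASum[l].end()) / ns;
    pBOut[l] = NumericVector(pBSum[l].begin(), pBSum[l].end()) / ns;
  }
  return List::create(_["post"] = post, _["pi"] = piOut,
                      _["pA"] = pAOut, _["pB"] = pBOut);
}
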