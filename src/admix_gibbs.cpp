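#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with uncorrelated cluster allele
// frequencies: per-gene-copy origins Z, cluster frequencies P ~ Dirichlet(lambda),
// individual ancestry Q ~ Dirichlet(alpha) with a common alpha given a
// Metropolis random-walk update under a uniform (0, alpha_max] hyperprior.
//
// geno: N x 2L integer matrix of allele codes (1-based), NA = missing.
// Returns posterior-mean Q and P, the retained log-likelihood trace, and the
// model log-probability estimate mean(lnL) - var(lnL)/2.

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
List admix_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles, int K,
                     int burnin, int sweeps, double lambda,
                     bool sample_alpha, double alpha_init, double alpha_max,
                     double alpha_sd) {
  const int N = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("genotype matrix must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");

  // P[k][l][j]
  std::vector<std::vector<std::vector<double> > > P(K);
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) P[k][l].assign(n_alleles[l], 1.0 / n_alleles[l]);
  }
  NumericMatrix Q(N, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  IntegerMatrix Z(N, 2 * L);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 2 * L; ++c)
      Z(i, c) = (int)std::floor(unif_rand() * K);

  double alpha = alpha_init;
  int alpha_acc = 0, alpha_try = 0;

  NumericMatrix Qsum(N, K);
  std::vector<std::vector<std::vector<double> > > Psum(P);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      std::fill(Psum[k][l].begin(), Psum[k][l].end(), 0.0);
  std::vector<double> lnl_trace;
  lnl_trace.reserve(sweeps);
  double alpha_sum = 0.0;

  std::vector<double> shape, draw, prob(K), qrow(K);

  for (int it = 0; it < burnin + sweeps; ++it) {
    // update P from origin-attributed allele counts
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        const int J = n_alleles[l];
        shape.assign(J, lambda);
        for (int i = 0; i < N; ++i) {
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a == NA_INTEGER) continue;
            if (Z(i, 2 * l + c) == k) shape[a - 1] += 1.0;
          }
        }
        draw.assign(J, 0.0);
        rdirichlet(shape, draw);
        P[k][l] = draw;
      }
    }
    // update Z
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == NA_INTEGER) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[k][l][a - 1];
            tot += prob[k];
          }
          double u = unif_rand() * tot, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { pick = k; break; }
          }
          Z(i, 2 * l + c) = pick;
        }
      }
    }
    // update Q
    for (int i = 0; i < N; ++i) {
      shape.assign(K, alpha);
      for (int c = 0; c < 2 * L; ++c) {
        int a = geno(i, c);
        if (a == NA_INTEGER) continue;
        shape[Z(i, c)] += 1.0;
      }
      rdirichlet(shape, qrow);
      for (int k = 0; k < K; ++k) Q(i, k) = qrow[k];
    }
    // Metropolis update of the common Dirichlet parameter alpha
    if (sample_alpha && K > 1) {
      double prop = alpha + norm_rand() * alpha_sd;
      ++alpha_try;
      if (prop > 0.0 && prop <= alpha_max) {
        double lr = 0.0;
        lr += N * (R::lgammafn(K * prop) - K * R::lgammafn(prop));
        lr -= N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            slq += std::log(std::max(Q(i, k), 1e-12));
        lr += (prop - alpha) * slq;
        if (std::log(unif_rand()) < lr) { alpha = prop; ++alpha_acc; }
      }
    }
    // retained-sweep accumulation
    if (it >= burnin) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        for (int l = 0; l < L; ++l) {
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a == NA_INTEGER) continue;
            double m = 0.0;
            for (int k = 0; k < K; ++k) m += Q(i, k) * P[k][l][a - 1];
            ll += std::log(std::max(m, 1e-300));
          }
        }
      }
      lnl_trace.push_back(ll);
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int j = 0; j < n_alleles[l]; ++j) Psum[k][l][j] += P[k][l][j];
      alpha_sum += alpha;
    }
  }

  const double ns = (double)sweeps;
  for (int i = 0; i < N; ++i) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) { Qsum(i, k) /= ns; rs += Qsum(i, k); }
    for (int k = 0; k < K; ++k) Qsum(i, k) /= rs;
  }
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k) {
      double rs = 0.0;
      for (int j = 0; j < n_alleles[l]; ++j) { pm(k, j) = Psum[k][l][j] / ns; rs += pm(k, j); }
      for (int j = 0; j < n_alleles[l]; ++j) pm(k, j) /= rs;
    }
    Pout[l] = pm;
  }
  NumericVector lnl(lnl_trace.begin(), lnl_trace.end());
  double mu = mean(lnl);
  double v = ns > 1 ? var(lnl) : 0.0;
  return List::create(_["Q"] = Qsum, _["P"] = Pout, _["lnL"] = lnl,
                      _["lnPX"] = mu - v / 2.0,
                      _["alpha"] = alpha_sum / ns,
                      _["alpha_accept"] = alpha_try > 0 ? (double)alpha_acc / alpha_try : NA_REAL);
}
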