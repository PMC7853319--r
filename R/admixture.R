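#' Fit the Bayesian admixture model
#'
#' Gibbs sampler for the admixture model with uncorrelated cluster allele
#' frequencies: each gene copy carries a latent cluster origin Z, cluster
#' allele frequencies P have a Dirichlet(`lambda`) prior, individual ancestry
#' vectors Q a symmetric Dirichlet(alpha) prior, and the common alpha is
#' given a Metropolis random-walk update under a uniform (0, `alpha_max`]
#' hyperprior. Missing genotypes are skipped in the likelihood. The model
#' log-probability estimate is `mean(lnL) - var(lnL)/2` over retained sweeps,
#' the standard harmonic-style approximation used for Delta-K model choice.
#'
#' Full-scale runs in the literature use 1e4 burn-in and 5e5 sampling sweeps;
#' the defaults here are scaled down (1e3 / 5e4) so that replicate runs and
#' simulations stay desk-sized. At the panel sizes this package targets (a
#' handful of loci, a few hundred individuals) the scaled runs are well past
#' convergence.
#'
#' @param g a [genotype_matrix].
#' @param K number of clusters (>= 1).
#' @param burnin,sweeps burn-in and retained sweeps.
#' @param lambda Dirichlet prior on cluster allele frequencies.
#' @param sample_alpha update alpha by Metropolis (default) or keep fixed.
#' @param alpha_init,alpha_max,alpha_sd initial value, hyperprior upper bound
#'   and proposal s.d. for alpha.
#' @param seed optional stream seed.
#' @return An `admixture_result`: `K`, `Q` (N x K posterior means, rows sum
#'   to 1), `P` (per-locus cluster allele frequencies), `lnPX`, `lnL` trace,
#'   `alpha`, `seed`, and `diagnostics` (Geweke z per chain statistic).
#' @export
fit_admixture <- function(g, K, burnin = 1000, sweeps = 50000,
                          lambda = 1, sample_alpha = TRUE, alpha_init = 1,
                          alpha_max = 10, alpha_sd = 0.25, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), K >= 1)
  nal <- n_alleles(g)
  n_distinct <- nrow(unique(as.data.frame(g$alleles)))
  if (K > n_distinct)
    warning("K exceeds the number of distinct multilocus genotypes (", n_distinct, ")")
  fit <- with_seed(seed,
    admix_gibbs_cpp(g$alleles, nal, as.integer(K), as.integer(burnin),
                    as.integer(sweeps), lambda, sample_alpha, alpha_init,
                    alpha_max, alpha_sd))
  rownames(fit$Q) <- g$individuals
  gz <- geweke_z(fit$lnL)
  if (is.finite(gz) && abs(gz) > 3)
    warning("lnL trace fails the Geweke check (|z| = ", round(abs(gz), 1),
            "); consider longer burn-in")
  structure(list(K = as.integer(K), Q = fit$Q, P = fit$P, lnPX = fit$lnPX,
                 lnL = fit$lnL, alpha = fit$alpha, seed = seed,
                 diagnostics = list(geweke_z = gz,
                                    alpha_accept = fit$alpha_accept)),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("<admixture_result> K = ", x$K, ", N = ", nrow(x$Q),
      ", lnPX = ", round(x$lnPX, 2), "\n", sep = "")
  invisible(x)
}

# Geweke convergence diagnostic on the retained lnL trace: z-score between
# the first 10% and last 50%, with a crude spectral-density-at-zero estimate
# from batch means.
geweke_z <- function(x) {
  n <- length(x)
  if (n < 100) return(NA_real_)
  a <- x[seq_len(floor(0.1 * n))]
  b <- x[seq.int(ceiling(0.5 * n), n)]
  bm_var <- function(v) {
    nb <- max(10L, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    mns <- vapply(seq_len(nb), function(i) mean(v[((i - 1) * bs + 1):(i * bs)]), 1.0)
    stats::var(mns) / nb   # variance of the mean of v from batch means
  }
  va <- bm_var(a)
  vb <- bm_var(b)
  if (va + vb <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Evanno Delta-K table from replicate admixture runs
#'
#' For replicate runs over a consecutive K range, computes mean and s.d. of
#' the model log-probability `lnPX`, the successive differences L'(K), the
#' absolute second differences |L''(K)|, and
#' `Delta-K = |mean lnPX(K+1) - 2 mean lnPX(K) + mean lnPX(K-1)| / sd(lnPX(K))`.
#' Delta-K is defined only at interior K values.
#'
#' @param results list of `admixture_result` objects (replicates over a K
#'   range), or a data frame with columns `K` and `lnPX`.
#' @return An `evanno_table` data frame: `K`, `reps`, `mean_lnPX`, `sd_lnPX`,
#'   `Lprime`, `Lsecond`, `deltaK`.
#' @export
evanno_delta_k <- function(results) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- data.frame(K = vapply(results, `[[`, 1L, "K"),
                     lnPX = vapply(results, `[[`, 1.0, "lnPX"))
  }
  ks <- sort(unique(df$K))
  if (length(ks) < 3L || !all(diff(ks) == 1L))
    stop("need at least 3 consecutive K values")
  reps <- vapply(ks, function(k) sum(df$K == k), 1L)
  if (any(reps < 2L)) stop("need >= 2 replicates per K")
  mu <- vapply(ks, function(k) mean(df$lnPX[df$K == k]), 1.0)
  s <- vapply(ks, function(k) stats::sd(df$lnPX[df$K == k]), 1.0)
  if (any(s == 0)) stop("sd(lnPX) is zero for some K; Delta-K undefined")
  nk <- length(ks)
  lp <- c(NA, diff(mu))
  ls <- rep(NA_real_, nk)
  dk <- rep(NA_real_, nk)
  for (i in 2:(nk - 1L)) {
    # |mean lnPX(K+1) - 2 mean lnPX(K) + mean lnPX(K-1)| / sd(lnPX(K))
    ls[i] <- abs(mu[i + 1L] - 2 * mu[i] + mu[i - 1L])
    dk[i] <- ls[i] / s[i]
  }
  structure(data.frame(K = ks, reps = reps, mean_lnPX = mu, sd_lnPX = s,
                       Lprime = lp, Lsecond = ls, deltaK = dk),
            class = c("evanno_table", "data.frame"))
}

#' Align and average replicate admixture runs
#'
#' Cluster labels are arbitrary in mixture models; replicate runs are aligned
#' to the first run by the column permutation maximizing the summed column
#' dot-products (searched exactly over all K! permutations for K <= 6, which
#' covers the use cases here), then averaged element-wise. Rows of the result
#' still sum to 1.
#'
#' @param runs list of N x K Q matrices (or `admixture_result`s) with equal
#'   shapes.
#' @return The aligned, averaged Q matrix.
#' @export
align_replicates <- function(runs) {
  qs <- lapply(runs, function(r) if (inherits(r, "admixture_result")) r$Q else as.matrix(r))
  d <- dim(qs[[1]])
  for (q in qs) if (!identical(dim(q), d)) stop("Q matrices differ in shape")
  K <- d[2]
  perms <- permutations_of(K)
  ref <- qs[[1]]
  acc <- ref
  for (r in qs[-1]) {
    best <- NULL
    best_s <- -Inf
    for (p in perms) {
      s <- sum(colSums(ref * r[, p, drop = FALSE]))
      if (s > best_s) { best_s <- s; best <- p }
    }
    acc <- acc + r[, best, drop = FALSE]
  }
  out <- acc / length(qs)
  out / rowSums(out)
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(K))
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
  out
}

#' Hybrid index from a two-cluster admixture model
#'
#' Fits K = 2 admixture models in replicate, aligns and averages them, and
#' reports each individual's Q for the reference cluster, where the reference
#' cluster is the one with the highest mean Q among designated species-A
#' individuals. Values near 1 are species-A-like, near 0 species-B-like and
#' near 0.5 F1-like; a mixture of pure parents and F1s gives the classic
#' trimodal hybrid-zone histogram.
#'
#' @param g a [genotype_matrix] restricted to the two parental species and
#'   their putative hybrids.
#' @param ref_ids ids of designated species-A individuals (defines index 1).
#' @param reps number of replicate K = 2 runs (20 at full scale).
#' @param third_party_ids optional ids known to belong to a third species;
#'   their presence triggers a warning, not an error.
#' @param ... passed to [fit_admixture()] (e.g. `burnin`, `sweeps`).
#' @param seed optional stream seed.
#' @return A named numeric vector of hybrid indices in \[0, 1\].
#' @export
hybrid_index <- function(g, ref_ids, reps = 20, third_party_ids = NULL,
                         seed = NULL, ...) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(ref_ids %in% g$individuals)) stop("unknown reference ids")
  if (!is.null(third_party_ids) && any(third_party_ids %in% g$individuals))
    warning("subset contains pure individuals of a third species")
  runs <- lapply(seq_len(reps), function(r)
    fit_admixture(g, K = 2, seed = fan_seed(seed, r), ...))
  Q <- align_replicates(runs)
  ref_col <- which.max(colMeans(Q[g$individuals %in% ref_ids, , drop = FALSE]))
  stats::setNames(Q[, ref_col], g$individuals)
}
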