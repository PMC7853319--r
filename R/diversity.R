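#' Per-locus molecular diversity statistics
#'
#' Computes the number of segregating sites `S`, Watterson's theta and
#' nucleotide diversity pi from a haplotype alignment. A column contributes to
#' `S` only if every character in it is one of A, C, G, T (columns touched by
#' `N` or a gap are excluded, a conservative convention). Watterson's theta is
#' `S / a_n` with `a_n = sum(1/i, i = 1..n-1)`, reported per locus by default.
#' Pi is the mean pairwise difference, computed with pairwise deletion of
#' non-ACGT sites and reported per site by default.
#'
#' @param aln a [hap_alignment] with at least two sequences.
#' @param per_site if `TRUE` (default) report `pi` per site and `theta_w` per
#'   locus (the reporting convention of standard summary tables); if `FALSE`
#'   both are per-locus totals.
#' @return A data frame with one row: `n`, `sites`, `S`, `theta_w`, `pi`.
#' @export
diversity_stats <- function(aln, per_site = TRUE) {
  stopifnot(inherits(aln, "hap_alignment"))
  n <- length(aln$seq)
  if (n < 2L) stop("need at least two sequences")
  m <- do.call(rbind, strsplit(aln$seq, ""))
  L <- ncol(m)
  clean <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  S <- sum(vapply(which(clean), function(j) length(unique(m[, j])) > 1L, TRUE))
  a_n <- sum(1 / seq_len(n - 1L))
  theta <- S / a_n
  # mean pairwise difference with pairwise deletion
  tot <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
      nsite <- sum(ok)
      d <- if (nsite > 0) sum(m[i, ok] != m[j, ok]) / nsite else NA_real_
      if (!is.na(d)) {
        tot <- tot + if (per_site) d else d * nsite
        np <- np + 1L
      }
    }
  }
  pi <- if (np > 0) tot / np else NA_real_
  data.frame(n = n, sites = L, S = S, theta_w = theta, pi = pi,
             locus = aln$locus, stringsAsFactors = FALSE)
}

#' Permutation G-test of linkage disequilibrium between two loci
#'
#' Tests association between the genotype classes at two loci by a
#' log-likelihood-ratio (G) statistic on the two-locus genotype contingency
#' table, with the null distribution obtained by permuting one locus's
#' genotypes across individuals. The p-value `(1 + #{G* >= G}) / (n_perm + 1)`
#' has resolution `1/(n_perm + 1)`. Individuals missing either genotype are
#' dropped.
#'
#' @param gA,gB genotype columns: character vectors (e.g. `"1/2"`) or factors,
#'   one entry per individual; or a [genotype_matrix] plus locus indices via
#'   [ld_pairs()].
#' @param n_perm number of permutations (>= 99).
#' @param seed optional stream seed.
#' @return A list of class `ld_result`: `G`, `p`, `n_perm`, `testable` and
#'   `n` (individuals used). A monomorphic locus gives `testable = FALSE`
#'   with `p = NA` (distinct from p = 1).
#' @export
ld_test <- function(gA, gB, n_perm = 9999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  keep <- !is.na(gA) & !is.na(gB)
  gA <- factor(as.character(gA[keep]))
  gB <- factor(as.character(gB[keep]))
  out <- list(G = NA_real_, p = NA_real_, n_perm = as.integer(n_perm),
              testable = TRUE, n = length(gA))
  class(out) <- "ld_result"
  if (nlevels(gA) < 2L || nlevels(gB) < 2L) {
    out$testable <- FALSE
    return(out)
  }
  ia <- as.integer(gA)
  ib <- as.integer(gB)
  nA <- nlevels(gA)
  nB <- nlevels(gB)
  # margins are invariant under permutation, so expected counts are fixed
  E <- outer(tabulate(ia, nA), tabulate(ib, nB)) / length(ia)
  g_stat <- function(b) {
    tab <- tabulate(ia + nA * (b - 1L), nA * nB)
    keep <- tab > 0L
    2 * sum(tab[keep] * log(tab[keep] / E[keep]))
  }
  with_seed(seed, {
    G <- g_stat(ib)
    ge <- 0L
    for (r in seq_len(n_perm)) {
      if (g_stat(sample(ib)) >= G - 1e-12) ge <- ge + 1L
    }
    out$G <- G
    out$p <- (1 + ge) / (n_perm + 1)
    out
  })
}

#' All pairwise LD tests in a genotype matrix
#'
#' @param g a [genotype_matrix].
#' @param n_perm permutations per test.
#' @param seed optional stream seed.
#' @return Data frame with one row per locus pair: `locusA`, `locusB`, `G`,
#'   `p`, `testable`, plus `q` from [qvalues()] over the testable pairs.
#' @export
ld_pairs <- function(g, n_perm = 9999, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  L <- length(g$loci)
  geno_str <- function(l) {
    a <- g$alleles[, 2L * l - 1L]
    b <- g$alleles[, 2L * l]
    ifelse(is.na(a), NA_character_, paste0(a, "/", b))
  }
  cols <- lapply(seq_len(L), geno_str)
  res <- list()
  k <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      k <- k + 1L
      t <- ld_test(cols[[i]], cols[[j]], n_perm = n_perm,
                   seed = fan_seed(seed, k))
      res[[k]] <- data.frame(locusA = g$loci[i], locusB = g$loci[j],
                             G = t$G, p = t$p, testable = t$testable,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  if (any(out$testable)) out$q[out$testable] <- qvalues(out$p[out$testable])
  out
}

#' Storey q-values for false-discovery control
#'
#' Computes q-values `q_i = pi0 * min_{p_j >= p_i} (m * p_j / rank_j)`. The
#' null proportion `pi0` is estimated by the smoother method (natural cubic
#' spline of `pi0(lambda)` over `lambda = 0.05, 0.10, ..., 0.95`, evaluated at
#' the largest lambda and clipped to (0, 1]). For small batches (`m < 20`,
#' e.g. the 9-14-test LD tables this package targets) the estimate is
#' unstable, so `pi0 = 1` is used, which reduces to Benjamini-Hochberg.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @param pi0 optionally fix `pi0` instead of estimating it.
#' @return Vector of q-values, same order as `pvals`.
#' @export
qvalues <- function(pvals, pi0 = NULL) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20L) {
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), 1.0)
      fit <- stats::smooth.spline(lam, pi0l, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p)
  ro <- order(o)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q[ro], 1)
}
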