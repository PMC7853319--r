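#' Genotype likelihood under a hybrid category
#'
#' The per-locus likelihood of an observed genotype `g = (i, j)` under a
#' genotype-frequency class phi is
#' `P(g | phi) = phi[1] * HW(g | pA) + phi[2] * Mix(g | pA, pB) + phi[3] * HW(g | pB)`
#' where `HW(g | p)` is the Hardy-Weinberg genotype probability (`p_i^2` for
#' a homozygote, `2 p_i p_j` otherwise) and
#' `Mix(g | pA, pB) = pA_i pB_i` for a homozygote and
#' `pA_i pB_j + pA_j pB_i` otherwise. Summed over all genotypes this is 1 for
#' any phi and frequency vectors.
#'
#' @param genotype integer pair of allele codes (unordered).
#' @param pA,pB allele-frequency vectors of the two parental species.
#' @param phi category triple, or a matrix of triples (one row per category).
#' @return Likelihood value(s), one per row of `phi`. An allele absent from
#'   both frequency vectors legally gives likelihood 0 (flagged via attribute
#'   `absent_allele`).
#' @export
category_likelihood <- function(genotype, pA, pB, phi = hybrid_categories()) {
  stopifnot(length(genotype) == 2L)
  if (is.null(dim(phi))) phi <- matrix(phi, 1)
  i <- genotype[1]; j <- genotype[2]
  if (max(i, j) > length(pA) || max(i, j) > length(pB))
    stop("allele code outside frequency vector")
  if (i == j) {
    hwA <- pA[i]^2; hwB <- pB[i]^2; mix <- pA[i] * pB[i]
  } else {
    hwA <- 2 * pA[i] * pA[j]; hwB <- 2 * pB[i] * pB[j]
    mix <- pA[i] * pB[j] + pA[j] * pB[i]
  }
  out <- as.vector(phi %*% c(hwA, mix, hwB))
  names(out) <- rownames(phi)
  if (pA[i] + pB[i] == 0 || pA[j] + pB[j] == 0)
    attr(out, "absent_allele") <- TRUE
  out
}

#' Bayesian assignment to six hybrid categories
#'
#' Assigns each non-reference individual a posterior probability over the six
#' genotype-frequency classes of [hybrid_categories()] by Gibbs sampling:
#' category indicators are updated given the current parental allele
#' frequencies and mixing proportions, gene copies are stochastically
#' attributed to a parental species given the category, and the parental
#' frequencies are redrawn from their Dirichlet(1) posterior given the
#' designated pure reference individuals plus the attributed copies. Loci are
#' treated as unlinked; missing genotypes contribute likelihood 1.
#'
#' By default the category mixing proportions are sampled with a Dirichlet(1)
#' prior, as in the standard implementation of this model; `pi = "uniform"`
#' fixes them at 1/6, and a numeric vector fixes them at given values. With
#' `method = "plugin"` no MCMC is run: parental frequencies are fixed at the
#' pure-sample maximum-likelihood estimates and the posterior is proportional
#' to the product of [category_likelihood()] across loci under fixed uniform
#' (or supplied) category weights; on fully diagnostic panels this matches
#' the MCMC posterior and serves as its enumeration oracle.
#'
#' @param g a [genotype_matrix] of the individuals to classify.
#' @param pure_a,pure_b [genotype_matrix] objects (or ids into `g`) of
#'   designated pure reference individuals; required, disjoint.
#' @param burnin,sweeps MCMC run lengths (full-scale convention 1e4 / 5e5;
#'   scaled-down defaults as in [fit_admixture()]).
#' @param pi `"sample"`, `"uniform"`, or a fixed probability vector.
#' @param method `"mcmc"` or `"plugin"`.
#' @param seed optional stream seed.
#' @return A `category_posterior`: matrix (individuals x 6) of posterior
#'   probabilities, rows summing to 1, with attributes recording settings.
#' @export
fit_newhybrids <- function(g, pure_a, pure_b, burnin = 1000, sweeps = 50000,
                           pi = "sample", method = c("mcmc", "plugin"),
                           seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  if (!inherits(pure_a, "genotype_matrix")) pure_a <- g[g$individuals %in% pure_a]
  if (!inherits(pure_b, "genotype_matrix")) pure_b <- g[g$individuals %in% pure_b]
  if (length(pure_a$individuals) == 0L || length(pure_b$individuals) == 0L)
    stop("need pure reference individuals for both species")
  if (length(intersect(pure_a$individuals, pure_b$individuals)))
    stop("label collision: individuals designated pure for both species")
  if (length(pure_a$individuals) < 5L || length(pure_b$individuals) < 5L)
    warning("fewer than 5 pure references for a species; frequency estimates will be weak")
  if (!identical(pure_a$loci, g$loci) || !identical(pure_b$loci, g$loci))
    stop("reference loci differ from sample loci")
  phi <- hybrid_categories()
  nal <- pmax(n_alleles(g), n_alleles(pure_a), n_alleles(pure_b))

  if (method == "plugin") {
    w <- if (identical(pi, "sample") || identical(pi, "uniform"))
      rep(1 / 6, 6) else rep_len(as.numeric(pi), 6) / sum(pi)
    freq <- function(ref) lapply(seq_along(nal), function(l) {
      cnt <- tabulate(ref$alleles[, c(2L * l - 1L, 2L * l)], nal[l])
      if (sum(cnt) == 0) rep(1 / nal[l], nal[l]) else cnt / sum(cnt)
    })
    pA <- freq(pure_a); pB <- freq(pure_b)
    post <- t(vapply(seq_along(g$individuals), function(i) {
      ll <- log(w)
      for (l in seq_along(g$loci)) {
        gt <- g$alleles[i, c(2L * l - 1L, 2L * l)]
        if (anyNA(gt)) next
        lik <- category_likelihood(gt, pA[[l]], pB[[l]], phi)
        ll <- ll + log(pmax(lik, 1e-300))
      }
      pr <- exp(ll - max(ll))
      pr / sum(pr)
    }, numeric(6)))
  } else {
    sample_pi <- identical(pi, "sample")
    pi_fixed <- if (identical(pi, "uniform") || sample_pi) rep(1 / 6, 6)
                else rep_len(as.numeric(pi), 6) / sum(pi)
    fit <- with_seed(seed,
      nh_gibbs_cpp(g$alleles, pure_a$alleles, pure_b$alleles, nal, phi,
                   as.integer(burnin), as.integer(sweeps), sample_pi,
                   pi_fixed, 1.0))
    post <- fit$post
  }
  dimnames(post) <- list(g$individuals, rownames(phi))
  structure(post, class = c("category_posterior", "matrix"),
            settings = list(method = method, burnin = burnin, sweeps = sweeps,
                            pi = pi, seed = seed))
}

#' Call hybrid classes at a critical posterior threshold
#'
#' The class with the maximum posterior is called if and only if its
#' posterior is `>= threshold` (ties at the threshold are called, a
#' documented convention); otherwise the individual is reported as "mixed".
#'
#' @param post a `category_posterior` (or plain matrix, rows on the simplex).
#' @param threshold critical posterior probability in (0.5, 1].
#' @return A `call_table` data frame: `id`, `call`, `posterior`, `threshold`.
#' @export
assign_threshold <- function(post, threshold = 0.85) {
  stopifnot(threshold > 0.5, threshold <= 1)
  p <- unclass(post)
  best <- max.col(p, ties.method = "first")
  bp <- p[cbind(seq_len(nrow(p)), best)]
  call <- ifelse(bp >= threshold, colnames(p)[best], "mixed")
  data.frame(id = rownames(p), call = call, posterior = bp,
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Sort individuals into crosses from a three-cluster admixture matrix
#'
#' Individuals with any cluster Q at or above `pure_threshold` are labelled
#' pure for that cluster; all others are assigned to the cross between their
#' two top-ranked clusters. An exact tie between the top clusters is broken
#' by the lower cluster index and flagged.
#'
#' @param Q3 N x 3 admixture matrix (rows summing to 1).
#' @param pure_threshold Q threshold for calling an individual pure.
#' @return Data frame: `id`, `label` (`"pure-<k>"` or `"cross-<i>-<j>"`),
#'   `tied` flag.
#' @export
sort_crosses <- function(Q3, pure_threshold = 0.90) {
  Q3 <- as.matrix(Q3)
  if (ncol(Q3) != 3L) stop("need a K = 3 Q matrix")
  if (any(abs(rowSums(Q3) - 1) > 1e-6)) stop("Q rows must sum to 1")
  ids <- rownames(Q3)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(Q3)))
  out <- data.frame(id = ids, label = NA_character_, tied = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(Q3))) {
    q <- Q3[i, ]
    o <- order(-q, seq_along(q))   # ties broken by cluster index
    if (q[o[1]] >= pure_threshold) {
      out$label[i] <- paste0("pure-", o[1])
    } else {
      pair <- sort(o[1:2])
      out$label[i] <- paste0("cross-", pair[1], "-", pair[2])
      if (q[o[2]] == q[o[3]] || q[o[1]] == q[o[2]]) out$tied[i] <- TRUE
    }
  }
  out
}
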