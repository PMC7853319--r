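test_that("diversity statistics match hand enumeration", {
  same <- hap_alignment(rep("ACGTACGT", 4))
  d0 <- diversity_stats(same)
  expect_identical(d0$S, 0L)
  expect_equal(d0$theta_w, 0)
  expect_equal(d0$pi, 0)

  # (AAA, AAT, ATT): S = 2, a_3 = 1.5 -> theta = 1.333 per locus;
  # pairwise diffs (1, 2, 1)/3 sites -> pi = 0.4444 per site
  aln <- hap_alignment(c("AAA", "AAT", "ATT"))
  d <- diversity_stats(aln)
  expect_identical(d$S, 2L)
  expect_equal(d$theta_w, 2 / 1.5)
  expect_equal(d$pi, (1 / 3 + 2 / 3 + 1 / 3) / 3)
  dl <- diversity_stats(aln, per_site = FALSE)
  expect_equal(dl$pi, 4 / 3)

  # n = 4 with 11 segregating sites: theta = 11 / (1 + 1/2 + 1/3) = 6
  base <- strsplit(paste(rep("A", 11), collapse = ""), "")[[1]]
  seqs <- vapply(1:4, function(i) {
    s <- base
    if (i > 1) s[((i - 2) * 4 + 1):min(11, (i - 1) * 4)] <- "T"
    paste(s, collapse = "")
  }, "")
  d4 <- diversity_stats(hap_alignment(seqs))
  expect_identical(d4$S, 11L)
  expect_equal(d4$theta_w, 6)

  expect_error(diversity_stats(hap_alignment("ACGT")), "two sequences")

  # columns touched by N or gaps are excluded from S, pairwise-deleted in pi
  dn <- diversity_stats(hap_alignment(c("AN-T", "ACGT", "TCGT")))
  expect_identical(dn$S, 1L)
})

test_that("theta and pi agree in expectation under neutral panmixia", {
  # independent oracle: coalescent genealogies from ape::rcoal with Poisson
  # mutations on branches; both statistics estimate twice the mutation rate
  set.seed(11)
  mu <- 0.4
  th <- pi_hat <- numeric(200)
  for (r in 1:200) {
    tr <- ape::rcoal(6)
    # one binary site per mutation, A -> T, sites independent
    n_mut <- rpois(length(tr$edge.length), mu * tr$edge.length)
    tips <- matrix("A", 6, max(1, sum(n_mut)))
    col <- 0
    for (e in seq_along(n_mut)) {
      if (n_mut[e] == 0) next
      desc <- phangorn::Descendants(tr, tr$edge[e, 2], "tips")[[1]]
      for (k in seq_len(n_mut[e])) {
        col <- col + 1
        tips[desc, col] <- "T"
      }
    }
    aln <- hap_alignment(apply(tips, 1, paste, collapse = ""))
    d <- diversity_stats(aln, per_site = FALSE)
    th[r] <- d$theta_w
    pi_hat[r] <- d$pi
  }
  # E[theta_w] = E[pi] = 2 * mu under this genealogy scaling
  expect_equal(mean(th), mean(pi_hat), tolerance = 0.08)
  expect_equal(mean(th), 2 * mu, tolerance = 0.15)
})

test_that("the permutation G-test behaves as an exact-style test", {
  # monomorphic locus is not testable (distinct from p = 1)
  r <- ld_test(rep("1/1", 10), c(rep("1/2", 5), rep("2/2", 5)), n_perm = 99)
  expect_false(r$testable)
  expect_true(is.na(r$p))

  # perfectly co-varying genotypes: only ties can match the maximal G
  gA <- rep(c("1/1", "1/2", "2/2", "1/3"), each = 5)
  r2 <- ld_test(gA, gA, n_perm = 9999, seed = 1)
  expect_true(r2$testable)
  expect_lte(r2$p, 0.001)

  # Monte-Carlo p close to the exact enumeration p on a tiny sample
  set.seed(2)
  gA6 <- c("1/1", "1/1", "1/2", "2/2", "1/2", "2/2")
  gB6 <- c("1/2", "1/1", "1/1", "2/2", "2/2", "1/2")
  g_of <- function(b) {
    ta <- factor(gA6); tb <- factor(b)
    tab <- table(ta, tb)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    2 * sum(tab[tab > 0] * log(tab[tab > 0] / E[tab > 0]))
  }
  idx <- trihyb:::permutations_of(6)
  gs <- vapply(idx, function(p) g_of(gB6[p]), 1.0)
  exact_p <- mean(gs >= g_of(gB6) - 1e-12)
  mc <- ld_test(gA6, gB6, n_perm = 9999, seed = 3)
  expect_equal(mc$p, exact_p, tolerance = 0.02)

  # null uniformity and Type-I control on independent loci
  set.seed(4)
  pvals <- replicate(400, {
    a <- paste0(sample(1:2, 30, TRUE), "/", sample(1:2, 30, TRUE))
    b <- paste0(sample(1:2, 30, TRUE), "/", sample(1:2, 30, TRUE))
    r <- ld_test(a, b, n_perm = 199)
    if (r$testable) r$p else NA_real_
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(pvals)))
})

test_that("q-values implement the step-up estimator with pi0", {
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # all p = 1 collapse to pi0
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(qvalues(rep(1, 5), pi0 = 0.7), rep(0.7, 5))
  # Benjamini-Hochberg by hand at pi0 = 1
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1), rep(0.04, 4))
  # monotone in p; bounded below by p * pi0 after ranking
  set.seed(5)
  p <- runif(40)
  q <- qvalues(p, pi0 = 0.8)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p * 0.8 - 1e-12))
  # smoother estimate stays in (0, 1]
  q2 <- qvalues(c(runif(30, 0, 0.05), runif(30)))
  expect_true(all(q2 >= 0 & q2 <= 1))
})

test_that("pairwise LD tables attach q-values over testable pairs", {
  set.seed(6)
  g <- random_genotypes(n = 30, loci = 4, max_allele = 3, miss = 0.05)
  tab <- ld_pairs(g, n_perm = 199, seed = 7)
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$p[tab$testable] > 0 & tab$p[tab$testable] <= 1))
  expect_true(all(!is.na(tab$q[tab$testable])))
})
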