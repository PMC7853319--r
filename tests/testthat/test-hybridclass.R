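test_that("category likelihoods match hand evaluation and normalise", {
  phi <- hybrid_categories()
  # fixed differences: het (1,2) is certain under F1, impossible under pureA
  lik <- category_likelihood(c(1, 2), pA = c(1, 0), pB = c(0, 1), phi)
  expect_equal(unname(lik["F1"]), 1)
  expect_equal(unname(lik["pureA"]), 0)
  # worked F2 example: 0.25 * 0.81 + 0.5 * 0.18 + 0.25 * 0.04
  l2 <- category_likelihood(c(1, 1), pA = c(0.9, 0.1), pB = c(0.2, 0.8),
                            phi["F2", , drop = FALSE])
  expect_equal(unname(l2), 0.3025)
  # total probability over all genotypes is 1 for any phi and frequencies
  set.seed(1)
  for (r in 1:5) {
    pA <- rgamma(4, 1); pA <- pA / sum(pA)
    pB <- rgamma(4, 1); pB <- pB / sum(pB)
    phi_r <- rgamma(3, 1); phi_r <- phi_r / sum(phi_r)
    tot <- 0
    for (i in 1:4) for (j in i:4)
      tot <- tot + category_likelihood(c(i, j), pA, pB, phi_r)
    expect_equal(unname(tot), 1)
  }
})

test_that("plug-in posteriors equal brute-force enumeration", {
  pan <- make_panel(2, 2, diagnosticity = 1)
  refA <- simulate_cross(pan, "pureA", 10, seed = 1)
  refB <- simulate_cross(pan, "pureB", 10, seed = 2)
  # homozygous A at both of 2 loci: P(pureA) = 1 / (1 + 1/16 + 1/4) = 16/21
  unk <- genotype_matrix(matrix(c(1L, 1L, 1L, 1L), 1), "u", names(pan))
  post <- fit_newhybrids(unk, refA, refB, method = "plugin", pi = "uniform")
  expect_equal(unname(post[1, "pureA"]), 16 / 21)
  # brute-force check of the full posterior over the six categories
  phi <- hybrid_categories()
  liks <- apply(phi, 1, function(p)
    category_likelihood(c(1, 1), c(1, 0), c(0, 1), matrix(p, 1))^2)
  expect_equal(unname(post[1, ]), unname(liks / sum(liks)))

  # >= 1 AA and >= 1 BB homozygote on diagnostic loci forces F2
  unk2 <- genotype_matrix(matrix(c(1L, 1L, 2L, 2L), 1), "u", names(pan))
  post2 <- fit_newhybrids(unk2, refA, refB, method = "plugin", pi = "uniform")
  expect_equal(unname(post2[1, "F2"]), 1)

  # all-heterozygote on 4 diagnostic loci: F1 posterior 1/(1 + 3/16)
  pan4 <- make_panel(4, 2, diagnosticity = 1)
  unk3 <- genotype_matrix(matrix(rep(c(1L, 2L), 4), 1), "u", names(pan4))
  post3 <- fit_newhybrids(unk3, simulate_cross(pan4, "pureA", 10, seed = 3),
                          simulate_cross(pan4, "pureB", 10, seed = 4),
                          method = "plugin", pi = "uniform")
  expect_equal(unname(post3[1, "F1"]), 16 / 19)
})

test_that("reference handling enforces the module contract", {
  pan <- make_panel(4, 2, diagnosticity = 1)
  refA <- simulate_cross(pan, "pureA", 10, seed = 1)
  refB <- simulate_cross(pan, "pureB", 10, seed = 2)
  unk <- simulate_cross(pan, "F1", 3, seed = 3)
  expect_error(fit_newhybrids(unk, refA[0], refB, method = "plugin"), "pure reference")
  expect_error(fit_newhybrids(unk, refA, refA, method = "plugin"), "collision")
  expect_warning(fit_newhybrids(unk, refA[1:3], refB, method = "plugin"),
                 "fewer than 5")
})

test_that("missing data and locus order do not distort posteriors", {
  pan <- make_panel(4, 2, diagnosticity = 1)
  refA <- simulate_cross(pan, "pureA", 20, seed = 5)
  refB <- simulate_cross(pan, "pureB", 20, seed = 6)
  # fully missing individual: uniform posterior (missing = likelihood 1)
  unk <- genotype_matrix(matrix(NA_integer_, 1, 8), "u", names(pan))
  post <- fit_newhybrids(unk, refA, refB, method = "plugin", pi = "uniform")
  expect_equal(unname(post[1, ]), rep(1 / 6, 6))
  # exchangeability under locus permutation
  al <- matrix(c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 2L), 1)
  g1 <- genotype_matrix(al, "u", names(pan))
  perm <- c(3, 1, 4, 2)
  al2 <- al[, as.vector(rbind(2 * perm - 1, 2 * perm)), drop = FALSE]
  g2 <- genotype_matrix(al2, "u", names(pan))
  p1 <- fit_newhybrids(g1, refA, refB, method = "plugin", pi = "uniform")
  refA2 <- genotype_matrix(refA$alleles[, as.vector(rbind(2 * perm - 1, 2 * perm))],
                           refA$individuals, names(pan))
  refB2 <- genotype_matrix(refB$alleles[, as.vector(rbind(2 * perm - 1, 2 * perm))],
                           refB$individuals, names(pan))
  p2 <- fit_newhybrids(g2, refA2, refB2, method = "plugin", pi = "uniform")
  expect_equal(unname(p1), unname(p2))
})

test_that("MCMC and plug-in posteriors agree on diagnostic panels", {
  # large reference panels so the sampled frequencies approach the fixed
  # plug-in estimates (the Dirichlet(1) prior contributes ~1/(2n) mass)
  pan <- make_panel(4, 2, diagnosticity = 1)
  refA <- simulate_cross(pan, "pureA", 1000, seed = 7)
  refB <- simulate_cross(pan, "pureB", 1000, seed = 8)
  unk <- do.call(rbind, lapply(c("pureA", "F1", "F2", "bcA"), function(cl)
    simulate_cross(pan, cl, 10, seed = 30 + match(cl, rownames(hybrid_categories())))))
  pp <- fit_newhybrids(unk, refA, refB, method = "plugin", pi = "uniform")
  pm <- fit_newhybrids(unk, refA, refB, method = "mcmc", pi = "uniform",
                       burnin = 1000, sweeps = 20000, seed = 9)
  tv <- max(0.5 * rowSums(abs(unclass(pp) - unclass(pm))))
  expect_lte(tv, 0.05)
})

test_that("posteriors concentrate on the true class as loci accumulate", {
  post_true <- sapply(c(4, 8, 16), function(L) {
    pan <- make_panel(L, 2, diagnosticity = 1)
    refA <- simulate_cross(pan, "pureA", 50, seed = L)
    refB <- simulate_cross(pan, "pureB", 50, seed = L + 1)
    f2 <- simulate_cross(pan, "F2", 40, seed = L + 2)
    post <- fit_newhybrids(f2, refA, refB, method = "plugin", pi = "uniform")
    mean(post[, "F2"])
  })
  expect_true(all(diff(post_true) > 0))
  expect_gt(post_true[3], 0.8)
})

test_that("threshold calls and cross sorting follow their conventions", {
  post <- matrix(c(1, 0, 0, 0, 0, 0,
                   0.78, 0.1, 0.04, 0.04, 0.02, 0.02,
                   0.85, 0.03, 0.03, 0.03, 0.03, 0.03),
                 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), rownames(hybrid_categories())))
  post <- post / rowSums(post)
  post[3, ] <- c(0.85, 0.03, 0.03, 0.03, 0.03, 0.03)  # exact threshold row
  calls <- assign_threshold(post, 0.85)
  expect_identical(calls$call, c("pureA", "mixed", "pureA"))
  expect_error(assign_threshold(post, 0.4), "0.5")

  q <- rbind(c(0.95, 0.03, 0.02),
             c(0.50, 0.45, 0.05),
             c(0.45, 0.45, 0.10))
  sc <- sort_crosses(q)
  expect_identical(sc$label, c("pure-1", "cross-1-2", "cross-1-2"))
  expect_true(sc$tied[3])
  expect_false(any(sc$tied[1:2]))
  expect_error(sort_crosses(rbind(c(0.5, 0.2, 0.2))), "sum to 1")
})
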