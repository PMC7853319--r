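test_that("the admixture sampler recovers known population structure", {
  # K = 1: every Q entry exactly 1
  pan <- make_panel(4, 2, diagnosticity = 1)
  g <- rbind(simulate_cross(pan, "pureA", 10, seed = 1),
             simulate_cross(pan, "pureB", 10, seed = 2))
  f1 <- fit_admixture(g, K = 1, burnin = 100, sweeps = 500, seed = 3)
  expect_true(all(f1$Q == 1))

  # two populations fixed for alternate alleles: own-cluster Q >= 0.95
  g2 <- rbind(simulate_cross(pan, "pureA", 20, seed = 4),
              simulate_cross(pan, "pureB", 20, seed = 5))
  f2 <- suppressWarnings(fit_admixture(g2, K = 2, burnin = 500, sweeps = 5000, seed = 6))
  expect_true(all(abs(rowSums(f2$Q) - 1) < 1e-9))
  expect_true(all(apply(f2$Q, 1, max) >= 0.95))
  own_a <- which.max(colMeans(f2$Q[1:20, ]))
  expect_true(all(f2$Q[1:20, own_a] >= 0.95))
  expect_true(all(f2$Q[21:40, 3 - own_a] >= 0.95))

  # simulated F1s added: their Q near 0.5 under the symmetric panel
  g3 <- rbind.genotype_matrix(g2, simulate_cross(pan, "F1", 20, seed = 7))
  f3 <- suppressWarnings(fit_admixture(g3, K = 2, burnin = 500, sweeps = 5000, seed = 8))
  expect_true(all(abs(f3$Q[41:60, 1] - 0.5) <= 0.1))

  # cluster allele frequencies live on the simplex
  for (pl in f2$P) expect_equal(unname(rowSums(pl)), rep(1, 2), tolerance = 1e-9)
})

test_that("mean absolute Q error is small on panels with known ancestry", {
  pan <- make_panel(4, 2, diagnosticity = 0.9)
  g <- rbind(simulate_cross(pan, "pureA", 20, seed = 11),
             simulate_cross(pan, "pureB", 20, seed = 12))
  f <- suppressWarnings(fit_admixture(g, K = 2, burnin = 500, sweeps = 10000, seed = 13))
  own_a <- which.max(colMeans(f$Q[1:20, ]))
  q_true <- c(rep(1, 20), rep(0, 20))
  err <- mean(abs(f$Q[, own_a] - q_true))
  expect_lte(err, 0.05)
})

test_that("Evanno Delta-K reproduces its arithmetic and recovers K = 3", {
  # direct arithmetic: means (-1000, -500, -490), sd(K=2) = 2 -> deltaK(2) = 245
  df <- data.frame(K = rep(1:3, each = 2),
                   lnPX = c(-1001, -999, -502, -498, -490.5, -489.5))
  df$lnPX[3:4] <- c(-500 - sqrt(2), -500 + sqrt(2))  # sd exactly 2
  ev <- evanno_delta_k(df)
  expect_equal(ev$deltaK[2], abs(-490 - 2 * -500 + -1000) / 2)
  # linear lnPX sequence: |L''| = 0 -> deltaK = 0
  lin <- data.frame(K = rep(1:3, each = 2),
                    lnPX = c(-30.1, -29.9, -20.1, -19.9, -10.1, -9.9))
  expect_equal(evanno_delta_k(lin)$deltaK[2], 0)
  expect_error(evanno_delta_k(df[df$K < 3, ]), "3 consecutive")
  expect_error(evanno_delta_k(data.frame(K = rep(1:3, each = 2),
                                         lnPX = rep(1:3, each = 2))), "sd")

  # recovery: three-species data with hybrids, K = 1..5
  pan3 <- make_panel(4, 6, diagnosticity = c(0.95, 0.9, 0.9),
                     species = c("A", "B", "C"))
  cfg <- data.frame(locality = "L1",
                    category = c("pureA", "pureB", "pureB", "F1", "F1", "F1"),
                    cross = c("A:B", "A:B", "B:C", "A:B", "A:C", "B:C"),
                    n = c(30, 30, 30, 12, 12, 12))
  ds <- simulate_dataset(cfg, pan3, seed = 21)
  runs <- list()
  for (K in 1:5) for (r in 1:3)
    runs[[length(runs) + 1]] <- suppressWarnings(
      fit_admixture(ds$genotypes, K, burnin = 300, sweeps = 3000,
                    seed = 100 * K + r))
  ev3 <- evanno_delta_k(runs)
  expect_identical(ev3$K[which.max(ev3$deltaK)], 3L)
  # lnPX rises to the true K and then stops improving
  expect_gt(ev3$mean_lnPX[3], ev3$mean_lnPX[2])
  expect_lt(ev3$mean_lnPX[5], ev3$mean_lnPX[3])
})

test_that("replicate alignment undoes label switching exactly", {
  set.seed(31)
  Q <- matrix(rgamma(30 * 3, 1), 30)
  Q <- Q / rowSums(Q)
  # identical runs average to themselves
  expect_equal(align_replicates(list(Q, Q)), Q)
  # a column-swapped copy is detected and undone
  expect_equal(align_replicates(list(Q, Q[, c(2, 1, 3)])), Q)
  # all 3! permutations of one run average back to the original
  perms <- trihyb:::permutations_of(3)
  runs <- lapply(perms, function(p) Q[, p])
  expect_equal(align_replicates(c(list(Q), runs)), Q, tolerance = 1e-12)
  expect_error(align_replicates(list(Q, Q[1:10, ])), "shape")
})

test_that("hybrid indices separate parents and centre F1s", {
  pan <- make_panel(4, 4, diagnosticity = 1)
  ga <- simulate_cross(pan, "pureA", 15, seed = 41)
  gb <- simulate_cross(pan, "pureB", 15, seed = 42)
  gf <- simulate_cross(pan, "F1", 15, seed = 43)
  g <- do.call(rbind, list(ga, gb, gf))
  expect_warning(
    hi <- hybrid_index(g, ref_ids = ga$individuals, reps = 3,
                       third_party_ids = c(gb$individuals[1]),
                       burnin = 200, sweeps = 2000, seed = 44),
    "third species")
  expect_true(all(hi >= 0 & hi <= 1))
  expect_true(all(hi[1:15] >= 0.9))
  expect_true(all(hi[16:30] <= 0.1))
  expect_true(all(abs(hi[31:45] - 0.5) <= 0.1))
})
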