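test_that("relative abundance converts counts to per-site proportions", {
  counts <- data.frame(
    locality = "L1", site = rep(c("s1", "s2"), each = 4),
    species = rep(c("w", "x", "y", "z"), 2),
    phase = "IP",
    count = c(10L, 30L, 40L, 20L, 5L, 0L, 0L, 0L))
  ra <- relative_abundance(counts)
  s1 <- ra$site[ra$site$site == "s1", ]
  expect_equal(s1$proportion[match(c("w", "x", "y", "z"), s1$species)],
               c(0.1, 0.3, 0.4, 0.2))
  expect_equal(sum(s1$proportion), 1)
  s2 <- ra$site[ra$site$site == "s2", ]
  expect_equal(s2$proportion[s2$species == "w"], 1.0)
  # empty site excluded with warning
  counts2 <- rbind(counts, data.frame(locality = "L1", site = "s3",
                                      species = "w", phase = "IP", count = 0L))
  expect_warning(relative_abundance(counts2), "empty")
  # phase filter restricts to adults before summing
  counts$phase <- rep(c("juvenile", "IP"), 4)
  ra2 <- suppressWarnings(relative_abundance(counts, phases = c("IP", "TP")))
  expect_true(all(ra2$site$species %in% c("x", "z")))
})

test_that("one-way ANOVA matches hand and brute-force sums of squares", {
  # {0.1, 0.2} vs {0.3, 0.4}: SSB = 0.04, SSW = 0.01, df = (1, 2), F = 8
  out <- anova_tukey(c(0.1, 0.2, 0.3, 0.4), c("a", "a", "b", "b"))
  expect_equal(out$F, 8)
  expect_equal(out$df, c(1, 2))
  # identical group means: F near zero
  null_f <- anova_tukey(c(0.1, 0.3, 0.1, 0.3), c("a", "a", "b", "b"))
  expect_equal(null_f$F, 0)
  expect_error(anova_tukey(c(1, 1, 2, 2), c("a", "a", "b", "b")), "variance")
  expect_error(anova_tukey(c(1, 2), c("a", "b")), "two observations")

  # brute-force SS decomposition on random fixtures, to 1e-10
  set.seed(7)
  for (r in 1:5) {
    y <- runif(18)
    gr <- rep(c("a", "b", "c"), each = 6)
    res <- anova_tukey(y, gr)
    gm <- mean(y)
    ssb <- sum(tapply(y, gr, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(y, gr, function(v) sum((v - mean(v))^2)))
    f_brute <- (ssb / 2) / (ssw / 15)
    expect_equal(res$F, f_brute, tolerance = 1e-10)
    # Tukey adjusted p-values are conservative relative to the unadjusted
    # pairwise contrast on the pooled error
    expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
    mse <- ssw / 15
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      d <- abs(mean(y[gr == pair[1]]) - mean(y[gr == pair[2]]))
      t_p <- 2 * pt(-d / sqrt(mse * (1 / 6 + 1 / 6)), 15)
      row <- grepl(pair[1], res$tukey$comparison) &
             grepl(pair[2], res$tukey$comparison)
      expect_gte(res$tukey$p_adj[row], t_p - 1e-9)
    }
  }
  # the arcsine transform flag changes the response, not the structure
  tr <- anova_tukey(c(0.1, 0.2, 0.3, 0.4), c("a", "a", "b", "b"),
                    transform = "asin_sqrt")
  expect_equal(tr$df, c(1, 2))
})

test_that("variety abundance scales genetic frequencies by adult counts", {
  adults <- data.frame(locality = c("L1", "L2"), adults = c(100L, 50L))
  calls <- data.frame(locality = rep("L1", 20),
                      variety = c(rep("X", 2), rep("nonhybrid", 18)))
  expect_warning(va <- variety_abundance(adults, calls, varieties = "X"),
                 "omitted")
  expect_equal(va$estimated_abundance[va$locality == "L1" & va$variety == "X"], 10)
  # no hybrids genotyped: estimated abundance zero
  calls0 <- data.frame(locality = "L1", variety = rep("nonhybrid", 10))
  va0 <- suppressWarnings(variety_abundance(adults, calls0, varieties = "X"))
  expect_equal(va0$estimated_abundance, 0)
  # linear in the adult count; estimates never exceed the count
  calls2 <- data.frame(locality = "L1",
                       variety = sample(c("X", "Y", "nonhybrid"), 40, TRUE))
  a1 <- suppressWarnings(variety_abundance(adults, calls2))
  a2 <- suppressWarnings(variety_abundance(transform(adults, adults = adults * 3), calls2))
  expect_equal(a2$estimated_abundance, 3 * a1$estimated_abundance)
  expect_lte(sum(a1$estimated_abundance), 100)
})

test_that("gonad summaries reproduce the printed reproductive table", {
  tab <- data.frame(
    species = c("S. compressus", "S. ghobban"),
    n = c(45L, 64L),
    male_IP = c(0L, 4L), male_TP = c(12L, 2L),
    female_IP = c(10L, 25L), female_TP = c(0L, 1L),
    active_male_IP = c(0L, 2L), active_male_TP = c(4L, 1L),
    active_female_IP = c(4L, 14L), active_female_TP = c(0L, 0L))
  gs <- gonad_summary(tab)
  # %SM: 22/45 -> 49 and 32/64 -> 50
  expect_identical(gs$pct_sm, c(49, 50))
  # 4 of 12 TP males active -> 33%; 4 of 10 IP females -> 40%
  expect_identical(gs$pct_active_male_TP[1], 33)
  expect_identical(gs$pct_active_female_IP[1], 40)
  # zero-sexed cells report NA, not 0
  expect_true(is.na(gs$pct_active_male_IP[1]))
  expect_identical(gs$pct_active_female_TP[2], 0)
  # all individuals sexed: %SM = 100
  full <- data.frame(species = "t", n = 4L, male_IP = 2L, male_TP = 0L,
                     female_IP = 2L, female_TP = 0L, active_male_IP = 1L,
                     active_male_TP = 0L, active_female_IP = 0L,
                     active_female_TP = 0L)
  expect_identical(gonad_summary(full)$pct_sm, 100)
  bad <- transform(tab, male_IP = c(40L, 40L))
  expect_error(gonad_summary(bad), "exceed")
})
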