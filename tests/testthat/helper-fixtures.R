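# shared fixture builders; everything is generated in code at test time

random_alignment <- function(n = 6, len = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
  hap_alignment(seqs, paste0("s", seq_len(n)), locus = "toy")
}

random_genotypes <- function(n = 10, loci = 3, max_allele = 5, miss = 0.1,
                             pops = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  al <- matrix(sample.int(max_allele, n * 2 * loci, TRUE), n)
  for (i in seq_len(n)) {
    for (l in seq_len(loci)) {
      if (runif(1) < miss) al[i, c(2 * l - 1, 2 * l)] <- NA
    }
  }
  genotype_matrix(al, sprintf("i%02d", seq_len(n)),
                  paste0("L", seq_len(loci)),
                  pop = rep_len(paste0("pop", seq_len(pops)), n))
}

# exhaustive minimum spanning tree weight by enumerating all spanning trees
# (Prufer sequences), for <= 6 nodes
brute_force_mst_weight <- function(D) {
  n <- nrow(D)
  if (n == 2) return(D[1, 2])
  prufer <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(prufer))) {
    seqp <- prufer[r, ]
    degree <- rep(1L, n) + tabulate(seqp, n)
    w <- 0
    s <- seqp
    deg <- degree
    for (k in seq_len(n - 2)) {
      leaf <- min(which(deg == 1L))
      w <- w + D[leaf, s[k]]
      deg[leaf] <- 0L
      deg[s[k]] <- deg[s[k]] - 1L
    }
    last <- which(deg == 1L)
    w <- w + D[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

# genotype equality up to individual order (Genepop groups individuals into
# population blocks) and population label names (Genepop/Structure keep only
# the partition, not the labels)
expect_same_genotypes <- function(g1, g2) {
  expect_setequal(g1$individuals, g2$individuals)
  ord <- match(g2$individuals, g1$individuals)
  expect_identical(unname(g1$alleles[ord, , drop = FALSE]),
                   unname(g2$alleles))
  expect_identical(g1$loci, g2$loci)
  if (!is.null(g1$pop) && !is.null(g2$pop)) {
    p1 <- as.integer(g1$pop)[ord]
    p2 <- as.integer(g2$pop)
    # same partition: relabelling by first occurrence must agree
    expect_identical(match(p1, unique(p1)), match(p2, unique(p2)))
  }
}
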