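#' Hybrid category definitions
#'
#' The six genotype-frequency classes used throughout the package, each
#' defined by phi = (P(both gene copies from species A), P(one copy from
#' each), P(both from species B)) at every locus:
#' pure A (1,0,0), pure B (0,0,1), F1 (0,1,0), F2 (0.25,0.5,0.25),
#' backcross to A (0.5,0.5,0) and backcross to B (0,0.5,0.5).
#'
#' @return A 6 x 3 numeric matrix with rownames
#'   `pureA, pureB, F1, F2, bcA, bcB`.
#' @export
hybrid_categories <- function() {
  phi <- rbind(pureA = c(1, 0, 0),
               pureB = c(0, 0, 1),
               F1   = c(0, 1, 0),
               F2   = c(0.25, 0.5, 0.25),
               bcA  = c(0.5, 0.5, 0),
               bcB  = c(0, 0.5, 0.5))
  colnames(phi) <- c("AA", "AB", "BB")
  phi
}

#' Build a species allele-frequency panel
#'
#' Each species has its own major allele at every locus. With diagnosticity
#' `d` and `a` alleles per locus, a species carries its major allele at
#' frequency `d + (1 - d)/a` and every other allele at `(1 - d)/a`, so `d = 1`
#' gives fixed differences and `d = 0` identical uniform frequencies.
#' `d` may be a single value or one value per species.
#'
#' @param n_loci number of unlinked loci.
#' @param alleles_per_locus number of allele codes per locus (>= number of
#'   species so each species can own a major allele).
#' @param diagnosticity value(s) in \[0, 1\].
#' @param species species labels; their order fixes which allele is major.
#' @return An `allele_panel`: list of per-locus matrices (species x allele)
#'   of frequencies.
#' @export
make_panel <- function(n_loci = 4, alleles_per_locus = 2,
                       diagnosticity = 0.95, species = c("A", "B")) {
  S <- length(species)
  if (alleles_per_locus < max(2L, S))
    stop("need at least max(2, n species) alleles per locus")
  d <- rep_len(diagnosticity, S)
  if (any(d < 0 | d > 1)) stop("diagnosticity must lie in [0, 1]")
  a <- alleles_per_locus
  freq <- matrix(NA_real_, S, a, dimnames = list(species, NULL))
  for (s in seq_len(S)) {
    freq[s, ] <- (1 - d[s]) / a
    freq[s, s] <- d[s] + (1 - d[s]) / a
  }
  panel <- rep(list(freq), n_loci)
  names(panel) <- paste0("locus", seq_len(n_loci))
  structure(panel, class = "allele_panel")
}

#' Build a two-species panel from explicit major-allele frequencies
#'
#' Constructor for marker panels stated as major-allele frequencies: each
#' species carries its own major allele (allele 1 for species A, allele 2 for
#' species B) at frequency `p_major`, with the remaining `1 - p_major` spread
#' equally over all other alleles. With `alleles_per_locus = 2` this is the
#' classic mirrored di-allelic marker; larger values emulate sequence-derived
#' haplotype alleles, where each species' minor variants are mostly private
#' rare haplotypes rather than the other species' major allele.
#'
#' @param n_loci number of loci.
#' @param p_major major-allele frequency in its own species.
#' @param alleles_per_locus total allele codes per locus (>= 2).
#' @param species two labels.
#' @return An `allele_panel`.
#' @export
make_panel_freq <- function(n_loci = 4, p_major = 0.95, alleles_per_locus = 2,
                            species = c("A", "B")) {
  stopifnot(p_major >= 0.5, p_major <= 1, length(species) == 2L,
            alleles_per_locus >= 2)
  a <- alleles_per_locus
  minor <- (1 - p_major) / (a - 1)
  freq <- rbind(rep(minor, a), rep(minor, a))
  freq[1, 1] <- p_major
  freq[2, 2] <- p_major
  rownames(freq) <- species
  panel <- rep(list(freq), n_loci)
  names(panel) <- paste0("locus", seq_len(n_loci))
  structure(panel, class = "allele_panel")
}

panel_species <- function(panel) rownames(panel[[1]])

sample_gamete_pure <- function(panel, sp) {
  vapply(panel, function(f) sample.int(ncol(f), 1L, prob = f[sp, ]), 1L)
}

# a pure individual: two independent gametes under Hardy-Weinberg
sample_pure_ind <- function(panel, sp) {
  rbind(sample_gamete_pure(panel, sp), sample_gamete_pure(panel, sp))
}

# pick one allele per locus from a 2 x L parent, carrying its origin label
gamete_of <- function(parent, origin) {
  pick <- sample(c(1L, 2L), ncol(parent), replace = TRUE)
  idx <- cbind(pick, seq_len(ncol(parent)))
  list(allele = parent[idx], origin = origin[idx])
}

#' Simulate individuals of one hybrid category by pedigree
#'
#' Individuals are produced by explicitly simulating their pedigree: pure
#' parents are drawn from the panel under Hardy-Weinberg; an F1 combines one
#' gamete from a pure A parent and one from a pure B parent; an F2 combines
#' gametes from two independently simulated F1s; a backcross combines an F1
#' gamete with a pure gamete. Sampling actual parents (rather than drawing
#' genotypes from the phi mixture locus by locus) preserves the
#' within-individual correlation of locus origins in F2s and backcrosses.
#'
#' @param panel an `allele_panel` for the two parental species.
#' @param category one of `"pureA"`, `"pureB"`, `"F1"`, `"F2"`, `"bcA"`,
#'   `"bcB"`.
#' @param n number of individuals.
#' @param seed optional seed (stream-local; global RNG state is restored).
#' @return A [genotype_matrix] with attribute `origin`, an `n x n_loci`
#'   matrix counting the gene copies of species-A origin (0, 1 or 2) at each
#'   locus, and attribute `maternal`, the species of the maternal line
#'   (the B-side parent is taken as the mother for F1s unless resampled by
#'   [simulate_dataset()]).
#' @export
simulate_cross <- function(panel, category, n, seed = NULL) {
  stopifnot(inherits(panel, "allele_panel"), n >= 1)
  category <- match.arg(category, rownames(hybrid_categories()))
  sp <- panel_species(panel)
  if (length(sp) < 2L) stop("panel must cover two species")
  L <- length(panel)
  with_seed(seed, {
    al <- matrix(NA_integer_, n, 2L * L)
    orig <- matrix(NA_integer_, n, L)
    for (i in seq_len(n)) {
      ind <- switch(category,
        pureA = {
          g <- sample_pure_ind(panel, sp[1])
          list(g = g, o = matrix("A", 2, L))
        },
        pureB = {
          g <- sample_pure_ind(panel, sp[2])
          list(g = g, o = matrix("B", 2, L))
        },
        F1 = make_f1(panel, sp),
        F2 = {
          f1a <- make_f1(panel, sp)
          f1b <- make_f1(panel, sp)
          ga <- gamete_of(f1a$g, f1a$o)
          gb <- gamete_of(f1b$g, f1b$o)
          list(g = rbind(ga$allele, gb$allele), o = rbind(ga$origin, gb$origin))
        },
        bcA = {
          f1 <- make_f1(panel, sp)
          gh <- gamete_of(f1$g, f1$o)
          list(g = rbind(gh$allele, sample_gamete_pure(panel, sp[1])),
               o = rbind(gh$origin, rep("A", L)))
        },
        bcB = {
          f1 <- make_f1(panel, sp)
          gh <- gamete_of(f1$g, f1$o)
          list(g = rbind(gh$allele, sample_gamete_pure(panel, sp[2])),
               o = rbind(gh$origin, rep("B", L)))
        })
      al[i, c(TRUE, FALSE)] <- ind$g[1, ]
      al[i, c(FALSE, TRUE)] <- ind$g[2, ]
      orig[i, ] <- colSums(ind$o == "A")
    }
    g <- genotype_matrix(al, sprintf("%s_%03d", category, seq_len(n)),
                         names(panel))
    attr(g, "origin") <- orig
    attr(g, "category") <- category
    g
  })
}

make_f1 <- function(panel, sp) {
  list(g = rbind(sample_gamete_pure(panel, sp[1]),
                 sample_gamete_pure(panel, sp[2])),
       o = rbind(rep("A", length(panel)), rep("B", length(panel))))
}

#' Simulate a full multi-locality, multi-class dataset
#'
#' Generates nuclear genotypes by [simulate_cross()] plus a maternally
#' inherited mitochondrial haplogroup per individual and sample metadata with
#' true class labels. The mitochondrial rule encodes strict maternal
#' inheritance: a pure individual carries its species haplogroup; an F1
#' carries its mother's species haplogroup, with the probability that the
#' mother belongs to the first species of the pair set by `p_mother_first`
#' (the strong asymmetries reported in field systems correspond to values
#' near 0 or 1); an F2's
#' haplogroup follows its F1 mother's maternal line; a backcross's mother is
#' the F1 parent with probability `p_mother_f1`, otherwise the pure parent.
#'
#' @param config data frame with columns `locality`, `category` and `n`
#'   (optionally `cross` naming a species pair "A:B" when the panel has more
#'   than two species).
#' @param panel an `allele_panel`.
#' @param p_mother_first probability the F1 founder's mother is the first
#'   species of the pair.
#' @param p_mother_f1 probability a backcross's mother is the F1 parent.
#' @param haplogroups named map species -> haplogroup label.
#' @param seed optional seed; the same seed and config reproduce the dataset.
#' @return A list of class `synthetic_dataset`: `genotypes`
#'   ([genotype_matrix]), `meta` (data frame with `id`, `locality`, `cross`,
#'   `true_class`, `mt_haplogroup`) and `provenance`.
#' @export
simulate_dataset <- function(config, panel, p_mother_first = 0.5,
                             p_mother_f1 = 0.5,
                             haplogroups = NULL, seed = NULL) {
  stopifnot(is.data.frame(config), nrow(config) > 0)
  sp <- panel_species(panel)
  if (is.null(haplogroups))
    haplogroups <- stats::setNames(LETTERS[seq_along(sp)], sp)
  if (is.null(config$cross)) config$cross <- paste(sp[1], sp[2], sep = ":")
  bad <- setdiff(unlist(strsplit(unique(config$cross), ":")), sp)
  if (length(bad)) stop("unknown species label in config: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    gs <- list(); metas <- list()
    for (r in seq_len(nrow(config))) {
      pair <- strsplit(config$cross[r], ":")[[1]]
      sub <- subset_panel(panel, pair)
      g <- simulate_cross(sub, config$category[r], config$n[r])
      mt <- maternal_haplogroup(config$category[r], config$n[r], pair,
                                p_mother_first, p_mother_f1, haplogroups)
      gs[[r]] <- g
      metas[[r]] <- data.frame(
        id = g$individuals, locality = config$locality[r],
        cross = config$cross[r], true_class = config$category[r],
        mt_haplogroup = mt, stringsAsFactors = FALSE)
    }
    g <- do.call(rbind.genotype_matrix, gs)
    meta <- do.call(rbind, metas)
    meta$id <- g$individuals
    g$pop <- factor(meta$locality)
    structure(list(genotypes = g, meta = meta,
                   provenance = list(seed = seed, config = config,
                                     p_mother_first = p_mother_first,
                                     p_mother_f1 = p_mother_f1)),
              class = "synthetic_dataset")
  })
}

subset_panel <- function(panel, pair) {
  structure(lapply(panel, function(f) f[pair, , drop = FALSE]),
            class = "allele_panel")
}

maternal_haplogroup <- function(category, n, pair, p_first, p_f1, haplogroups) {
  f1_mother <- function(n) ifelse(stats::runif(n) < p_first, pair[1], pair[2])
  mother_sp <- switch(category,
    pureA = rep(pair[1], n),
    pureB = rep(pair[2], n),
    F1 = f1_mother(n),
    F2 = f1_mother(n),                      # mother is an F1; follow her maternal line
    bcA = ifelse(stats::runif(n) < p_f1, f1_mother(n), rep(pair[1], n)),
    bcB = ifelse(stats::runif(n) < p_f1, f1_mother(n), rep(pair[2], n)))
  unname(haplogroups[mother_sp])
}

#' Expected fraction of fully heterospecific-heterozygous offspring under
#' mixed mating
#'
#' For a hypothetical species whose matings are intraspecific with
#' probability `s` and interspecific otherwise, and whose intraspecific
#' offspring are heterozygous for interspecific-type alleles at any one
#' diagnostic locus with probability `h`, the expected fraction of offspring
#' heterozygous at all `L` diagnostic loci is `(1 - s) + s * h^L`
#' (interspecific matings are assumed to yield full multilocus
#' heterozygotes). This is a deliberately simplified screening model for how
#' small the intraspecific mating rate would have to be to explain a sample
#' dominated by full multilocus heterozygotes.
#'
#' @param intra_prob probability `s` of intraspecific mating.
#' @param n_loci number of diagnostic loci `L`.
#' @param intra_het per-locus heterozygosity `h` of intraspecific offspring.
#' @return The expected all-locus heterozygote fraction.
#' @export
expected_all_het <- function(intra_prob, n_loci, intra_het) {
  stopifnot(intra_prob >= 0, intra_prob <= 1, intra_het >= 0, intra_het <= 1,
            n_loci >= 1)
  (1 - intra_prob) + intra_prob * intra_het^n_loci
}
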