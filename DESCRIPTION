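Package: trihyb
Title: Multilocus Inference for Multi-Species Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting hybrid zones among divergent species with
    small panels of co-dominant nuclear markers and a maternally inherited
    mitochondrial locus. Provides readers and writers for Genepop, Structure
    and CSV genotype tables and FASTA haplotype alignments; haplotype
    collapsing and minimum-spanning networks; per-locus diversity statistics
    (segregating sites, Watterson's theta, nucleotide diversity) and
    permutation tests of linkage disequilibrium with q-value false-discovery
    control; a Gibbs-sampler admixture model with Evanno Delta-K model-order
    selection, replicate alignment and hybrid indices; a six-category Bayesian
    hybrid-class classifier (pure, F1, F2 and backcrosses) with threshold
    calling and power simulation; mito-nuclear discordance and rate-asymmetry
    statistics; Bayes-factor comparison of migration models and coalescent
    simulation of reciprocal-monophyly probabilities; and ecological summaries
    of relative abundance and reproductive condition. A synthetic-data
    generator produces multilocus genotypes for pure species and hybrid
    classes so that every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
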