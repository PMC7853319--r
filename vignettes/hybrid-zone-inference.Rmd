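---
title: "Multilocus inference for multi-species hybrid zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus inference for multi-species hybrid zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trihyb)
```

## The problem

Several reef-fish systems consist of three or more divergent species that
hybridise wherever they co-occur, producing field phenotypes that have
historically been described as separate species. Resolving such a complex
from a small marker panel — typically a handful of phased nuclear loci
(sequence-derived, multi-allelic) plus a maternally inherited mitochondrial
locus — requires a chain of inferences: how many randomly mating clusters
the nuclear data support, which individuals are admixed, *how deep* the
hybridisation runs (F1 vs F2 vs backcross), how much confidence those depth
calls deserve given only four loci, which species the mothers were, whether
historical introgression or incomplete lineage sorting better explains
shared variation, and how abundant the hybrid varieties are in the field.
`trihyb` implements that chain end to end and ships a synthetic-data
generator so every stage is testable without the original deposits.

## Models

### Admixture (`fit_admixture`)

The standard Bayesian admixture model with uncorrelated cluster allele
frequencies: each gene copy carries a latent cluster origin; cluster
frequencies have a Dirichlet(λ = 1) prior; each individual's ancestry vector
Q has a symmetric Dirichlet(α) prior with a single α given a Metropolis
random-walk update under a uniform (0, 10] hyperprior. The model
log-probability is estimated as `mean(lnL) − var(lnL)/2` over retained
sweeps — the same approximation the field's standard tool reports, kept here
because the Evanno ΔK statistic is defined on it. Model order is chosen by
ΔK = |mean lnPX(K+1) − 2 mean lnPX(K) + mean lnPX(K−1)| / sd(lnPX(K)) over
replicate runs; replicate Q matrices are aligned by an exact search over all
K! column permutations (K ≤ 6) before averaging, which removes label
switching without the approximations a greedy matcher needs. Hybrid indices
are the averaged Q of a designated reference cluster from K = 2 fits.

A practical note baked into the tests: ΔK rewards the K at which replicate
runs *disagree least relative to the curvature of the fit*. On perfectly
clean simulated data every K fits deterministically and ΔK can spike at
K = 2; with hybrids in the sample and partially diagnostic markers — the
situation the method was designed for — replicate K = 2 runs alternate
between merge modes and ΔK correctly selects the true K = 3.

### Hybrid categories (`fit_newhybrids`)

Six genotype-frequency classes are defined by φ = (P(both gene copies from
species A), P(one from each), P(both from B)): pure A (1,0,0), pure B
(0,0,1), F1 (0,1,0), F2 (¼,½,¼), and the backcrosses (½,½,0) and (0,½,½).
The per-locus likelihood is
`P(g|φ) = φ₁·HW(g|pA) + φ₂·Mix(g|pA,pB) + φ₃·HW(g|pB)`, loci independent,
missing genotypes contributing likelihood 1. A Gibbs sampler alternates
category indicators, stochastic attribution of gene copies to parental
species, Dirichlet(1) updates of the parental frequencies informed by
designated pure references, and (by default) Dirichlet(1) updates of the
category mixing proportions π, as the original assignment program does;
`pi = "uniform"` fixes π instead. A `method = "plugin"` mode fixes the
frequencies at the pure-sample maximum-likelihood estimates and enumerates
the posterior directly; on fully diagnostic panels it is the exact oracle
the MCMC must match (total variation ≤ 0.05 in the acceptance suite, using
large reference panels so the Dirichlet prior's ~1/(2n) frequency shrinkage
is negligible). Calls use a critical posterior threshold (default 0.85,
ties called); individuals below it are "mixed".

### Power simulation (`run_power_sim`)

Known-class individuals are simulated by explicit pedigree (pure parents
drawn under Hardy–Weinberg; F1 = one gamete from each species; F2 = gametes
from two independent F1s; backcross = F1 gamete + pure gamete), which
preserves the within-individual correlation of locus origins that a
locus-by-locus φ-mixture draw would destroy. Rates follow the conventions of
the standard hybrid-detection workflow, stated explicitly because they are
rarely written out: efficiency = P(true class called as class), accuracy =
P(called-as-class is truly class), power = efficiency × accuracy, Type I =
P(non-member called as class), Type II = 1 − efficiency.

Two classification designs are provided. `"joint"` (default) classifies each
replicate's full equal-class mixture in one run. `"per_class"` classifies
each class's individuals in their own run, as happens when a field sample
dominated by one class is analysed. The choice matters enormously at small
L — see *Limitations*.

### Mito-nuclear layer

Haplogroups are assigned by minimum Hamming distance to reference sets built
from pure individuals (majority rule; exact ties are reported unassigned,
never silently broken). Discordance tables percentage the haplogroups of
each hybrid cross; under strict maternal inheritance they read out the
species of the founding mothers. Rate asymmetry between a species pair uses
three-taxon branch lengths solved from pairwise distances by the additive
three-point formulas, and
δ_a = mt_a/(mt_a+mt_b) − nuc_a/(nuc_a+nuc_b), with δ_b = −δ_a exactly. The
antisymmetry is a definitional invariant (every printed pair of δ values in
this literature has the ± structure); the choice of p-distance (default)
versus a Kimura two-parameter correction is exposed because the distance
model behind published branch lengths is usually unstated.

### Model comparison and lineage sorting

`lbf_table` performs the reproducible arithmetic layer of structured-
coalescent model choice: log Bayes factors `LBF_x = 2(lnmL_x − lnmL_{x−1})`
and posterior model probabilities via a stable log-sum-exp, consuming
printed log marginal likelihoods rather than re-estimating them (the MCMC
that produces them is deliberately out of scope). `monophyly_prob` simulates
a clean two-population split: n gene copies per species coalesce within
their population for the split time, remaining lineages merge ancestrally,
and the replicate succeeds iff the first between-population coalescence
happens after each side has collapsed to a single ancestor — an exact
characterisation of reciprocal monophyly that needs only lineage counts.

**Timescale calibration.** The split time is supplied as t/Ne with Ne the
diploid effective size; each locus experiences it on its own coalescent
timescale of `x·Ne/2` gene copies. Taking x = 1 for a maternally inherited
haploid locus (an effective count of Ne/2 breeding females) and x = 4 for
nuclear loci reproduces both classical 0.95-probability thresholds —
t/Ne ≥ 2.2 for one mitochondrial locus and ≥ 11.8 jointly for five nuclear
loci — within Monte-Carlo error at 10 sampled copies per species. The
alternative reading x = 2 for mtDNA gives P ≈ 0.66 at t/Ne = 2.2 and cannot
reproduce the published thresholds; x is a parameter so users can adopt
either convention knowingly.

### Ecology and reproduction

Site-level survey counts become per-site species proportions (empty sites
excluded with a warning), compared across localities by fixed-effects
one-way ANOVA with Tukey HSD; proportions are analysed untransformed by
default with an arcsine-square-root flag for sensitivity, because published
analyses of such data rarely state a transform. Hybrid-variety abundance is
the genetic-sample frequency of each variety times the locality's adult
(initial + terminal phase) count. Gonad tables yield %SM = 100·sexed/n and
per phase-sex activity percentages, rounded half-up to integers to match
printed tables; a cell with zero sexed individuals reports `NA`, not 0.

## The synthetic world

`make_panel(n_loci, alleles_per_locus, diagnosticity)` gives each species
its own major allele at frequency `d + (1−d)/a`, all other alleles at
`(1−d)/a`. Defaults emulate the study system this package is patterned on:
4 unlinked loci, 8 alleles per locus, d = 0.95 for crosses involving the
most divergent species and d = 0.8 for the youngest pair — multi-allelic
because the real markers are phased sequence haplotypes, whose minor
variants are mostly private rare haplotypes. A mirrored di-allelic reading
of "0.95/0.05 markers" is available (`make_panel_freq`) but behaves very
differently: at a mirrored SNP a within-species heterozygote *is* the
F1-type genotype, so pure-class power collapses, which the multi-allelic
panels avoid. Class counts, localities, maternal-origin probabilities
(`p_mother_first` near 0 or 1 produces the strong mito-nuclear asymmetries
seen in real crosses) and the seed are the stated world; the same seed and
configuration reproduce a dataset exactly, and one global seed fans out to
per-operation streams so subsets are reproducible.

What a green test does establish: Mendelian genotype proportions, φ
recovery from tracked gamete origins, locus independence, maternal
inheritance, and end-to-end recovery (ΔK = 3, trimodal hybrid indices,
pure/F1 separation). What it does not: linkage between markers, genotyping
error, phasing uncertainty, null alleles, or within-species population
structure — none of which the generator emulates.

## Numerical choices

- MCMC lengths: the field convention for these models is 1e4 burn-in /
  5e5 sweeps; package defaults are 1e3 / 5e4, which at 4 loci and a few
  hundred individuals are far past convergence (Geweke check on the lnL
  trace warns otherwise) and keep the full suite inside a desk-scale budget.
- Dirichlet draws clamp gamma variates at 1e-300 and renormalise; Q rows
  are renormalised so the simplex invariant holds to 1e-9.
- Haplotype codes are assigned by descending frequency, ties by first
  occurrence; minimum-spanning networks break ties by (distance, lower code
  pair) — both make outputs deterministic.
- Permutation p-values are `(1 + #{G* ≥ G})/(n_perm + 1)` with a 1e-12 tie
  guard; q-values fall back to Benjamini–Hochberg (π0 = 1) below 20 tests,
  where the smoother is unstable.
- Genepop uses the 3-digit diploid encoding with `000000` missing; allele
  codes above 999 are an error, not a silent truncation.

## Limitations

**The F1-power ceiling at four loci.** With L diagnostic loci, an F2 or
backcross pedigree produces a genotype indistinguishable from an F1 (one
A-pool and one B-pool allele at every locus) with probability (1/2)^L, and
for such a genotype the per-locus likelihood ratio of those categories
against F1 is never below 1/2 for any allele frequencies. Two consequences
at L = 4, independent of panel quality: (i) in a jointly classified
equal-class mixture the F1 posterior cannot exceed roughly
π_F1/(π_F1 + (1/16)·Σπ_comp) ≈ 0.82–0.87, straddling the conventional 0.85
calling threshold from below; (ii) F1 accuracy is capped at
n/(n + 3n/16) ≈ 0.84 at every threshold, because the mimics receive
identical posteriors. Joint-design F1 power at threshold 0.85 is therefore
≈ 0 here, while the same runs reproduce the low F2/backcross power
(≤ 0.40), the rare pure-class false positives (< 0.038) and the enumerated
F2 efficiency (0.4297) that published four-locus power analyses report. The
per-class design breaks the ceiling (the mixing proportions adapt to the
focal class, F1 power ≈ 0.9–1.0) but symmetrically inflates F2/backcross
power. Published claims of simultaneously high F1 power *and* low
F2/backcross power at four loci cannot be reproduced by any single
classification structure we could construct; both designs ship so users can
bracket the truth, and the acceptance suite pins the joint design's honest
numbers.

Other limitations: the δ statistic's distance model is an interpretation
(the antisymmetry and sign semantics are reproduced; published magnitudes
require the original alignments); the mixed-mating heterozygosity model
`(1−s) + s·h^L` is a declared simplified surrogate for an unavailable
supplementary derivation; structured-coalescent marginal likelihoods are
consumed, never estimated; and statistical-parsimony networks are replaced
by identity collapse plus a minimum-spanning tree, which can differ from a
parsimony network when loops matter.
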