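#' Haplogroup reference sets
#'
#' A `haplogroup_ref` maps disjoint haplogroup labels (e.g. the classic A, B,
#' C mitochondrial clades, each associated with one non-hybrid species) to
#' non-empty sets of reference haplotype sequences.
#'
#' @param groups named list of character vectors of equal-length reference
#'   sequences.
#' @param species optional named map haplogroup -> species.
#' @return A `haplogroup_ref` object.
#' @export
haplogroup_ref <- function(groups, species = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("haplogroups must be named")
  if (any(lengths(groups) == 0L)) stop("every haplogroup must be non-empty")
  seqs <- toupper(unlist(groups))
  if (length(unique(nchar(seqs))) != 1L)
    stop("reference sequences must share one length")
  if (anyDuplicated(seqs)) stop("haplogroups must be disjoint")
  structure(list(groups = lapply(groups, toupper), species = species,
                 width = nchar(seqs[1])),
            class = "haplogroup_ref")
}

#' Build haplogroup references from pure individuals
#'
#' Collects the haplotypes observed in designated pure individuals of each
#' species; a haplotype observed in more than one species is assigned to the
#' species where it is most frequent (majority rule) and dropped on an exact
#' tie.
#'
#' @param aln a [hap_alignment] of mitochondrial haplotypes.
#' @param species character vector, one species label per sequence.
#' @param labels optional haplogroup labels per species (defaults to A, B,
#'   ... in species order).
#' @return A [haplogroup_ref].
#' @export
build_haplogroup_refs <- function(aln, species, labels = NULL) {
  stopifnot(inherits(aln, "hap_alignment"),
            length(species) == length(aln$seq))
  sps <- unique(species)
  if (is.null(labels)) labels <- LETTERS[seq_along(sps)]
  groups <- stats::setNames(vector("list", length(sps)), labels)
  tab <- table(aln$seq, species)
  for (h in rownames(tab)) {
    cnt <- tab[h, sps]
    top <- which(cnt == max(cnt))
    if (length(top) == 1L)
      groups[[labels[top]]] <- c(groups[[labels[top]]], h)
  }
  haplogroup_ref(groups, species = stats::setNames(sps, labels))
}

#' Assign a haplotype to the nearest haplogroup
#'
#' Reports the haplogroup whose nearest reference member has the minimum
#' Hamming distance to the query, together with the margin to the runner-up
#' group. An exact tie between groups is reported as unassigned rather than
#' silently broken.
#'
#' @param seq query haplotype (same length as the references).
#' @param ref a [haplogroup_ref].
#' @return A list: `group` (label or `NA` on a tie), `distance`, `margin`,
#'   `tied`.
#' @export
assign_haplogroup <- function(seq, ref) {
  stopifnot(inherits(ref, "haplogroup_ref"))
  seq <- toupper(seq)
  if (nchar(seq) != ref$width) stop("query length differs from references")
  qs <- strsplit(seq, "")[[1]]
  dmin <- vapply(ref$groups, function(g)
    min(vapply(g, function(r) sum(strsplit(r, "")[[1]] != qs), 1L)), 1L)
  o <- order(dmin)
  tied <- length(dmin) > 1L && dmin[o[1]] == dmin[o[2]]
  list(group = if (tied) NA_character_ else names(dmin)[o[1]],
       distance = unname(dmin[o[1]]),
       margin = if (length(dmin) > 1L) unname(dmin[o[2]] - dmin[o[1]]) else Inf,
       tied = tied)
}

#' Mito-nuclear discordance table
#'
#' Cross-tabulates hybrid individuals by cross and mitochondrial haplogroup,
#' reporting percentages of non-missing haplogroups per cross (each row sums
#' to 100) with missing counts kept separately. Under strict maternal
#' inheritance these percentages read out the species of the mothers that
#' founded each hybrid cross.
#'
#' @param meta data frame with columns `cross` and `mt_haplogroup` (NA =
#'   missing), one row per hybrid individual.
#' @param haplogroups haplogroup labels fixing the column order.
#' @return A `discordance_table` data frame: `cross`, `n`, `n_missing`, one
#'   percentage column per haplogroup.
#' @export
discordance_table <- function(meta, haplogroups = c("A", "B", "C")) {
  stopifnot(all(c("cross", "mt_haplogroup") %in% names(meta)))
  crosses <- unique(meta$cross)
  rows <- lapply(crosses, function(cr) {
    hg <- meta$mt_haplogroup[meta$cross == cr]
    known <- hg[!is.na(hg)]
    if (length(known) == 0L)
      warning("no haplogrouped hybrids in cross ", cr)
    pct <- if (length(known)) 100 * as.vector(table(factor(known, haplogroups))) / length(known)
           else rep(NA_real_, length(haplogroups))
    df <- data.frame(cross = cr, n = length(known), n_missing = sum(is.na(hg)))
    df[haplogroups] <- as.list(pct)
    df
  })
  structure(do.call(rbind, rows),
            class = c("discordance_table", "data.frame"))
}

#' Three-taxon branch lengths from pairwise distances
#'
#' Solves the additive three-point equations
#' `bl_a = (d_ab + d_ac - d_bc) / 2` (and cyclic permutations) for the
#' external branch lengths of an unrooted three-taxon tree. A negative
#' solved branch means the distances are not additive and is an error.
#'
#' @param d_ab,d_ac,d_bc pairwise distances (>= 0).
#' @param taxa optional taxon labels.
#' @return Named numeric vector of three branch lengths.
#' @export
three_taxon_branch_lengths <- function(d_ab, d_ac, d_bc,
                                       taxa = c("a", "b", "c")) {
  stopifnot(d_ab >= 0, d_ac >= 0, d_bc >= 0)
  bl <- c((d_ab + d_ac - d_bc) / 2,
          (d_ab + d_bc - d_ac) / 2,
          (d_ac + d_bc - d_ab) / 2)
  if (any(bl < -1e-12))
    stop("additivity violated: negative branch length from these distances")
  stats::setNames(pmax(bl, 0), taxa)
}

#' Newick export of a three-taxon tree
#'
#' @param bl named branch lengths from [three_taxon_branch_lengths()].
#' @param path optional path to write the newick string to.
#' @return The newick string (invisibly if written to file).
#' @export
three_taxon_newick <- function(bl, path = NULL) {
  nwk <- sprintf("(%s:%g,%s:%g,%s:%g);", names(bl)[1], bl[1],
                 names(bl)[2], bl[2], names(bl)[3], bl[3])
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Pairwise distance between alignments of two groups
#'
#' Mean pairwise distance between all sequences of two groups, uncorrected
#' (p-distance) by default or with a Kimura two-parameter correction.
#'
#' @param aln a [hap_alignment].
#' @param groups character vector, one group label per sequence.
#' @param model `"raw"` (p-distance) or `"K80"`.
#' @return Symmetric matrix of mean between-group distances.
#' @export
group_distances <- function(aln, groups, model = c("raw", "K80")) {
  stopifnot(inherits(aln, "hap_alignment"), length(groups) == length(aln$seq))
  model <- match.arg(model)
  dna <- ape::as.DNAbin(strsplit(tolower(aln$seq), ""))
  D <- as.matrix(ape::dist.dna(dna, model = model, pairwise.deletion = TRUE))
  gs <- unique(groups)
  out <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (i == j) next
      out[i, j] <- mean(D[groups == gs[i], groups == gs[j]])
    }
  }
  out
}

#' Mitochondrial vs nuclear rate asymmetry (delta)
#'
#' For a species pair (a, b), the asymmetry statistic is the species' share
#' of mitochondrial branch length minus its share of nuclear branch length:
#' `delta_a = mt_a / (mt_a + mt_b) - nuc_a / (nuc_a + nuc_b)` and
#' `delta_b = -delta_a` exactly. A positive `delta_a` means species a's
#' mitochondrial genome has evolved disproportionately fast relative to its
#' nuclear genome - the precondition for asymmetric mito-nuclear
#' incompatibilities under Darwin's corollary to Haldane's rule.
#'
#' @param mt_bl,nuc_bl length-2 vectors of mitochondrial and nuclear branch
#'   lengths for species a and b (>= 0; each pair must have a positive sum).
#' @param pair species labels.
#' @return An `asymmetry_result` list: `pair`, `mt_bl`, `nuc_bl`, `delta`
#'   (named length-2 vector with `delta[a] == -delta[b]`).
#' @export
delta_asymmetry <- function(mt_bl, nuc_bl, pair = c("a", "b")) {
  stopifnot(length(mt_bl) == 2L, length(nuc_bl) == 2L,
            all(mt_bl >= 0), all(nuc_bl >= 0))
  if (sum(mt_bl) <= 0) stop("both mitochondrial branches are zero")
  if (sum(nuc_bl) <= 0) stop("both nuclear branches are zero")
  d_a <- mt_bl[1] / sum(mt_bl) - nuc_bl[1] / sum(nuc_bl)
  structure(list(pair = pair, mt_bl = mt_bl, nuc_bl = nuc_bl,
                 delta = stats::setNames(c(d_a, -d_a), pair)),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat("<asymmetry_result> delta[", x$pair[1], "] = ",
      format(x$delta[1], digits = 3), ", delta[", x$pair[2], "] = ",
      format(x$delta[2], digits = 3), "\n", sep = "")
  invisible(x)
}
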