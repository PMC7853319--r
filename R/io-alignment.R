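#' Haplotype alignment objects
#'
#' A `hap_alignment` holds equal-length nucleotide sequences (alphabet
#' `A,C,G,T,N,-`) with unique sample labels, typically one phased haplotype
#' per gene copy.
#'
#' @param sequences character vector of equal-length sequences.
#' @param labels character vector of unique sample labels.
#' @param locus optional locus name.
#' @return An object of class `hap_alignment` with elements `seq`, `labels`
#'   and `locus`.
#' @export
hap_alignment <- function(sequences, labels = NULL, locus = NA_character_) {
  if (length(sequences) == 0L) stop("empty alignment")
  sequences <- toupper(as.character(sequences))
  if (is.null(labels)) labels <- paste0("seq", seq_along(sequences))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("sequence labels must be unique")
  if (length(labels) != length(sequences)) stop("labels and sequences differ in length")
  len <- nchar(sequences)
  if (length(unique(len)) != 1L)
    stop("length mismatch: alignment is ragged (lengths ", paste(unique(len), collapse = ", "), ")")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("alphabet restricted to A,C,G,T,N,-: offending sequence(s) ",
         paste(labels[bad], collapse = ", "))
  structure(list(seq = sequences, labels = labels, locus = locus),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> ", length(x$seq), " sequences x ", nchar(x$seq[1]),
      " sites", if (!is.na(x$locus)) paste0(" [", x$locus, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.hap_alignment <- function(x) length(x$seq)

#' Read a FASTA alignment
#'
#' @param path path to a FASTA file.
#' @param locus optional locus name attached to the alignment.
#' @return A [hap_alignment]. Ragged input or an empty file is an error.
#' @export
read_alignment <- function(path, locus = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty input: no FASTA records in ", path)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  hap_alignment(seqs, names(dna), locus = locus)
}

#' Write a FASTA alignment
#'
#' @param aln a [hap_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  lines <- character(2L * length(aln$seq))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$labels)
  lines[c(FALSE, TRUE)] <- aln$seq
  writeLines(lines, path)
  invisible(path)
}

#' Collapse identical haplotypes into integer allele codes
#'
#' Identical sequences (compared literally, with no ambiguity expansion) share
#' one allele code. Codes are sequential integers starting at 1, assigned in
#' descending haplotype frequency with ties broken by first occurrence, which
#' makes the coding deterministic and keeps common alleles low-numbered.
#'
#' @param aln a [hap_alignment].
#' @return A list with `code_map` (named integer vector: haplotype sequence ->
#'   code), `counts` (integer vector indexed by code), `assignments`
#'   (per-input-sequence code) and `haplotypes` (sequence of each code).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (length(aln$seq) == 0L) stop("empty alignment")
  first <- match(unique(aln$seq), aln$seq)
  uniq <- aln$seq[first]
  cnt <- as.integer(table(factor(aln$seq, levels = uniq)))
  ord <- order(-cnt, first)
  haplotypes <- uniq[ord]
  counts <- cnt[ord]
  code_map <- stats::setNames(seq_along(haplotypes), haplotypes)
  assignments <- unname(code_map[aln$seq])
  names(counts) <- seq_along(counts)
  list(code_map = code_map, counts = counts,
       assignments = stats::setNames(assignments, aln$labels),
       haplotypes = haplotypes)
}
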