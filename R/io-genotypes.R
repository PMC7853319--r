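#' Multilocus co-dominant genotype matrices
#'
#' A `genotype_matrix` stores, for each individual and locus, an unordered
#' pair of positive-integer allele codes or a missing value. Pairs are stored
#' sorted ascending so that (2,1) and (1,2) are the same genotype; a missing
#' genotype has both entries `NA`.
#'
#' @param alleles integer matrix with `2 * n_loci` columns (two adjacent
#'   columns per locus) and one row per individual.
#' @param individuals character vector of individual ids.
#' @param loci character vector of locus names.
#' @param pop optional population / locality labels (recycled factor).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, individuals = NULL, loci = NULL, pop = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) %% 2L != 0L) stop("allele matrix needs two columns per locus")
  L <- ncol(alleles) / 2L
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(alleles)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  if (length(loci) != L) stop("locus names inconsistent with allele matrix")
  if (length(individuals) != nrow(alleles)) stop("individual ids inconsistent with allele matrix")
  if (any(alleles < 1L, na.rm = TRUE)) stop("allele codes must be >= 1")
  for (l in seq_len(L)) {
    a <- alleles[, 2L * l - 1L]
    b <- alleles[, 2L * l]
    if (any(xor(is.na(a), is.na(b))))
      stop("half-missing genotype at locus ", loci[l], "; missing genotypes need both entries NA")
    swap <- !is.na(a) & a > b
    if (any(swap)) {
      tmp <- a[swap]
      alleles[swap, 2L * l - 1L] <- b[swap]
      alleles[swap, 2L * l] <- tmp
    }
  }
  if (!is.null(pop)) pop <- factor(rep_len(pop, nrow(alleles)))
  dimnames(alleles) <- list(individuals,
                            paste0(rep(loci, each = 2L), c(".1", ".2")))
  structure(list(alleles = alleles, individuals = individuals,
                 loci = loci, pop = pop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$individuals), " individuals x ",
      length(x$loci), " loci", sep = "")
  if (!is.null(x$pop)) cat(" (", nlevels(x$pop), " populations)", sep = "")
  miss <- mean(is.na(x$alleles[, c(TRUE, FALSE), drop = FALSE]))
  cat("; missing ", round(100 * miss, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$individuals), length(x$loci))

#' Subset a genotype matrix by individuals
#' @param x a [genotype_matrix].
#' @param i row (individual) index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  genotype_matrix(x$alleles[i, , drop = FALSE], x$individuals[i], x$loci,
                  if (!is.null(x$pop)) x$pop[i])
}

#' Combine genotype matrices over individuals
#' @param ... [genotype_matrix] objects sharing the same loci.
#' @export
rbind.genotype_matrix <- function(...) {
  gs <- list(...)
  loci <- gs[[1]]$loci
  for (g in gs) if (!identical(g$loci, loci)) stop("locus sets differ")
  pops <- unlist(lapply(gs, function(g) {
    if (is.null(g$pop)) rep(NA_character_, length(g$individuals)) else as.character(g$pop)
  }))
  genotype_matrix(do.call(rbind, lapply(gs, `[[`, "alleles")),
                  make.unique(unlist(lapply(gs, `[[`, "individuals"))),
                  loci,
                  if (!all(is.na(pops))) pops)
}

n_alleles <- function(g) {
  vapply(seq_along(g$loci), function(l) {
    v <- g$alleles[, c(2L * l - 1L, 2L * l)]
    if (all(is.na(v))) 1L else max(v, na.rm = TRUE)
  }, 1L)
}

#' Read or write genotype files
#'
#' Supported dialects: `genepop` (3-digit diploid encoding, `000000` for
#' missing, one population block per label), `structure` (two rows per
#' individual, one gene copy per row, `-9` for missing) and `csv`
#' (`a1/a2` strings, empty for missing). All three round-trip genotypes,
#' missing data and population labels losslessly.
#'
#' @param g a [genotype_matrix] (for writing).
#' @param path file path.
#' @param dialect one of `"genepop"`, `"structure"`, `"csv"`.
#' @param title title line for Genepop output.
#' @return `read_genotypes()` returns a [genotype_matrix];
#'   `write_genotypes()` returns `path` invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("genepop", "structure", "csv"),
                            title = "trihyb genotypes") {
  stopifnot(inherits(g, "genotype_matrix"))
  dialect <- match.arg(dialect)
  L <- length(g$loci)
  pop <- if (is.null(g$pop)) factor(rep("pop1", length(g$individuals))) else g$pop
  if (dialect == "genepop") {
    if (any(g$alleles > 999L, na.rm = TRUE))
      stop("encoding error: allele code > 999 cannot be written as 3-digit Genepop")
    enc <- matrix("000", nrow(g$alleles), ncol(g$alleles))
    ok <- !is.na(g$alleles)
    enc[ok] <- formatC(g$alleles[ok], width = 3, flag = "0")
    gstr <- vapply(seq_len(nrow(enc)), function(i)
      paste(paste0(enc[i, c(TRUE, FALSE)], enc[i, c(FALSE, TRUE)]), collapse = " "), "")
    lines <- c(title, g$loci)
    for (p in levels(pop)) {
      lines <- c(lines, "Pop")
      idx <- which(pop == p)
      lines <- c(lines, paste0(g$individuals[idx], " ,  ", gstr[idx]))
    }
    writeLines(lines, path)
  } else if (dialect == "structure") {
    a1 <- g$alleles[, c(TRUE, FALSE), drop = FALSE]
    a2 <- g$alleles[, c(FALSE, TRUE), drop = FALSE]
    a1[is.na(a1)] <- -9L
    a2[is.na(a2)] <- -9L
    rows <- matrix("", 2L * nrow(a1), 2L + L)
    rows[c(TRUE, FALSE), ] <- cbind(g$individuals, as.character(as.integer(pop)),
                                    matrix(as.character(a1), nrow(a1)))
    rows[c(FALSE, TRUE), ] <- cbind(g$individuals, as.character(as.integer(pop)),
                                    matrix(as.character(a2), nrow(a2)))
    writeLines(c(paste(c("id", "pop", g$loci), collapse = "\t"),
                 apply(rows, 1, paste, collapse = "\t")), path)
  } else {
    df <- data.frame(id = g$individuals, pop = as.character(pop),
                     stringsAsFactors = FALSE)
    for (l in seq_len(L)) {
      a <- g$alleles[, 2L * l - 1L]
      b <- g$alleles[, 2L * l]
      df[[g$loci[l]]] <- ifelse(is.na(a), "", paste0(a, "/", b))
    }
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, dialect = c("genepop", "structure", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "genepop") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3L) stop("parse error: truncated Genepop file")
    pop_at <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
    if (length(pop_at) == 0L) stop("parse error: no Pop line in Genepop file")
    header <- lines[2:(pop_at[1] - 1L)]
    loci <- trimws(unlist(strsplit(header, ",")))
    loci <- loci[nzchar(loci)]
    ids <- character(); pops <- character(); rows <- list()
    pop_at <- c(pop_at, length(lines) + 1L)
    for (b in seq_len(length(pop_at) - 1L)) {
      block <- lines[(pop_at[b] + 1L):(pop_at[b + 1L] - 1L)]
      for (ln in block) {
        parts <- strsplit(ln, ",")[[1]]
        if (length(parts) < 2L) stop("parse error: malformed Genepop record: ", ln)
        id <- trimws(parts[1])
        fields <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
        if (length(fields) != length(loci))
          stop("parse error: ", id, " has ", length(fields), " genotypes for ",
               length(loci), " loci")
        if (any(nchar(fields) != 6L))
          stop("parse error: expected 3-digit diploid encoding for ", id)
        a <- as.integer(substr(fields, 1, 3))
        bb <- as.integer(substr(fields, 4, 6))
        a[a == 0L] <- NA_integer_; bb[bb == 0L] <- NA_integer_
        ids <- c(ids, id); pops <- c(pops, paste0("pop", b))
        rows[[length(rows) + 1L]] <- as.vector(rbind(a, bb))
      }
    }
    genotype_matrix(do.call(rbind, rows), ids, loci, pops)
  } else if (dialect == "structure") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(tab) < 3L) stop("parse error: malformed structure file header")
    loci <- colnames(tab)[-(1:2)]
    odd <- tab[c(TRUE, FALSE), , drop = FALSE]
    even <- tab[c(FALSE, TRUE), , drop = FALSE]
    if (!identical(odd[[1]], even[[1]]))
      stop("parse error: allele rows are not paired by individual")
    al <- matrix(NA_integer_, nrow(odd), 2L * length(loci))
    for (l in seq_along(loci)) {
      al[, 2L * l - 1L] <- as.integer(odd[[l + 2L]])
      al[, 2L * l] <- as.integer(even[[l + 2L]])
    }
    al[al == -9L] <- NA_integer_
    genotype_matrix(al, as.character(odd[[1]]), loci,
                    paste0("pop", odd[[2]]))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
    if (!all(c("id", "pop") %in% colnames(df)[1:2]))
      stop("parse error: csv dialect needs leading id,pop columns")
    loci <- colnames(df)[-(1:2)]
    al <- matrix(NA_integer_, nrow(df), 2L * length(loci))
    for (l in seq_along(loci)) {
      v <- df[[l + 2L]]
      has <- nzchar(v) & !is.na(v)
      parts <- strsplit(v[has], "/")
      al[has, 2L * l - 1L] <- as.integer(vapply(parts, `[`, "", 1L))
      al[has, 2L * l] <- as.integer(vapply(parts, `[`, "", 2L))
    }
    genotype_matrix(al, df$id, loci, df$pop)
  }
}
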