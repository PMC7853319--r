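#' Minimum-spanning haplotype network
#'
#' Builds a minimum-spanning tree over unique haplotypes under Hamming
#' distance (literal character comparison, so `N` and `-` count as ordinary
#' states). A deterministic Prim construction breaks ties by smallest
#' distance, then by the lower (from, to) code pair, so identical inputs
#' always give the same network. This is a simplified surrogate for
#' statistical-parsimony networks: it recovers the same backbone for small
#' divergences but imposes no connection limit.
#'
#' @param collapsed output of [collapse_haplotypes()], or a [hap_alignment]
#'   (which is collapsed first).
#' @return An object of class `hap_network`: list with `nodes` (data frame of
#'   `code`, `count`) and `edges` (data frame of `from`, `to`, `dist`).
#' @export
build_mst_network <- function(collapsed) {
  if (inherits(collapsed, "hap_alignment")) collapsed <- collapse_haplotypes(collapsed)
  haps <- collapsed$haplotypes
  counts <- collapsed$counts
  n <- length(haps)
  nodes <- data.frame(code = seq_len(n), count = as.integer(counts))
  if (n == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(), to = integer(),
                                             dist = integer())),
                     class = "hap_network"))
  }
  D <- hamming_matrix(haps)
  # Prim with deterministic tie-breaking on (distance, from, to)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- matrix(0L, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    best <- NULL
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        cand <- c(min(i, j), max(i, j), D[i, j])
        if (is.null(best) || cand[3] < best[3] ||
            (cand[3] == best[3] && (cand[1] < best[1] ||
                                    (cand[1] == best[1] && cand[2] < best[2]))))
          best <- cand
      }
    }
    edges[e, ] <- c(best[1], best[2], best[3])
    in_tree[best[1]] <- TRUE
    in_tree[best[2]] <- TRUE
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = edges[, 1], to = edges[, 2],
                                    dist = edges[, 3])),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> ", nrow(x$nodes), " haplotypes, ", nrow(x$edges),
      " edges, total weight ", sum(x$edges$dist), "\n", sep = "")
  invisible(x)
}

hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(m[i, ] != m[j, ])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}
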