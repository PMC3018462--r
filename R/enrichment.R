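#' @include AllClasses.R
NULL

#' Collapse probesets to unique gene ids
#'
#' Maps probeset ids to gene ids through an annotation table and removes
#' redundancy: several probesets measuring the same gene collapse to one
#' gene id. Probesets without gene annotation are dropped and counted —
#' pathway and pair analyses operate on genes, not probesets.
#'
#' @param probesetIds character vector of probeset ids.
#' @param annotation a data.frame or `DataFrame` with columns
#'   `probeset_id` and `gene_id` (missing gene ids as `NA` or `""`).
#' @return character vector of unique gene ids, with attribute
#'   `n_unannotated` counting the dropped probesets.
#' @export
#' @examples
#' anno <- data.frame(probeset_id = c("a", "b", "c"),
#'                    gene_id = c("G1", "G1", NA))
#' collapseToGenes(c("a", "b", "c"), anno)
collapseToGenes <- function(probesetIds, annotation) {
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("probeset_id", "gene_id") %in% colnames(annotation)))
  g <- annotation$gene_id[match(probesetIds, annotation$probeset_id)]
  bad <- is.na(g) | g == ""
  genes <- sort(unique(g[!bad]))
  attr(genes, "n_unannotated") <- sum(bad)
  genes
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' size-`n` draw from a universe of `N` genes, `K` of which belong to the
#' pathway, contains at least `k` pathway genes. Computed by summing the
#' point masses in log space (via `lchoose`) for numerical stability at
#' large counts; `k = 0` returns exactly 1.
#'
#' @param N universe size.
#' @param K pathway genes in the universe.
#' @param n selected (differentially expressed) genes.
#' @param k selected genes in the pathway.
#' @return the upper-tail probability.
#' @export
#' @examples
#' hypergeomUpperTail(10, 5, 4, 3)   # 55/210
hypergeomUpperTail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != round(c(N, K, n, k))) || any(c(N, K, n, k) < 0))
    stop("N, K, n, k must be non-negative integers")
  if (K > N || n > N) stop("K and n cannot exceed N")
  if (k > min(K, n)) stop("k cannot exceed min(K, n)")
  if (k == 0) return(1)
  i <- seq(k, min(K, n))
  lterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(.logSumExp(lterms)), 1)
}

#' Pathway over-representation among differentially expressed genes
#'
#' Hypergeometric over-representation of each pathway among the
#' differentially expressed genes. The universe is the annotated gene
#' content of the platform under test (`universeGenes`), not the genome:
#' the analysis is platform-specific by design. Only pathways whose
#' overlap with the selected genes strictly exceeds `minGenes` are
#' retained (mirroring the "greater than 15 / greater than 10 genes per
#' pathway" rule); retained pathways are tested and reported sorted by
#' p value, with raw p values — no multiple-testing correction.
#'
#' @param deGenes character, differentially expressed gene ids (must be a
#'   subset of `universeGenes`).
#' @param universeGenes character, annotated genes on the platform.
#' @param pathways named list of gene-id vectors (see [readGMT()]).
#' @param minGenes strict lower cutoff on the pathway's DE-gene count.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with columns `pathway`, `N`, `K`, `n`, `k`,
#'   `p_value`, `significant`, sorted by `p_value`.
#' @export
enrichPathways <- function(deGenes, universeGenes, pathways,
                           minGenes = 15L, alpha = 0.05) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  universeGenes <- unique(universeGenes)
  if (!all(deGenes %in% universeGenes))
    stop("deGenes must be a subset of universeGenes")
  empty <- data.frame(pathway = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(deGenes)) {
    warning("no differentially expressed genes; empty enrichment result")
    return(empty)
  }
  N <- length(universeGenes)
  n <- length(unique(deGenes))
  rows <- lapply(names(pathways), function(pw) {
    K <- length(intersect(pathways[[pw]], universeGenes))
    k <- length(intersect(pathways[[pw]], deGenes))
    if (k <= minGenes) return(NULL)
    data.frame(pathway = pw, N = N, K = K, n = n, k = k,
               p_value = hypergeomUpperTail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  res$significant <- res$p_value < alpha
  rownames(res) <- NULL
  res
}
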