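#' @include AllClasses.R
NULL

#' Orientation breakdown of a probeset list
#'
#' Counts probesets per orientation class (sense, antisense, unassigned)
#' and renders each class's share of the total, half-up rounded.
#'
#' @param annotation data.frame or `DataFrame` with `probeset_id` and
#'   `orientation`.
#' @param probesetIds optional subset of probesets to tally (default: all
#'   annotated probesets).
#' @param decimals decimal places for percentages (default 2).
#' @return data.frame with columns `orientation`, `count`, `percent`.
#' @export
orientationBreakdown <- function(annotation, probesetIds = NULL,
                                 decimals = 2L) {
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("probeset_id", "orientation") %in% colnames(annotation)))
  if (!is.null(probesetIds))
    annotation <- annotation[annotation$probeset_id %in% probesetIds, ,
                             drop = FALSE]
  lev <- c("sense", "antisense", "unassigned")
  cnt <- table(factor(annotation$orientation, levels = lev))
  total <- sum(cnt)
  if (total == 0L) stop("no probesets to tally")
  data.frame(orientation = lev,
             count = as.integer(cnt),
             percent = roundHalfUp(100 * as.integer(cnt) / total, decimals),
             stringsAsFactors = FALSE)
}

#' Deduplicate probesets of one orientation to gene ids
#'
#' Restricts an annotation (optionally to a probeset subset) to one
#' orientation, drops probesets without gene annotation, and collapses the
#' rest to unique gene ids — redundant probesets of the same gene count
#' once.
#'
#' @param annotation data.frame or `DataFrame` with `probeset_id`,
#'   `gene_id`, `orientation`.
#' @param orientation `"sense"` or `"antisense"`.
#' @param probesetIds optional probeset subset.
#' @return character vector of unique gene ids with attribute
#'   `n_unannotated`.
#' @export
dedupeByGene <- function(annotation, orientation, probesetIds = NULL) {
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("probeset_id", "gene_id", "orientation") %in%
                  colnames(annotation)))
  orientation <- match.arg(orientation, c("sense", "antisense"))
  if (!is.null(probesetIds))
    annotation <- annotation[annotation$probeset_id %in% probesetIds, ,
                             drop = FALSE]
  annotation <- annotation[annotation$orientation == orientation, ,
                           drop = FALSE]
  collapseToGenes(annotation$probeset_id, annotation)
}

#' Classify the overlap geometry of a cis-NAT pair
#'
#' For two opposite-strand transcripts at one locus: `fully_overlapping`
#' when one interval contains the other (containment takes precedence,
#' since it satisfies both end conditions); otherwise `head_to_head` when
#' the overlap interval contains both transcripts' 5' ends, `tail_to_tail`
#' when it contains both 3' ends, and `non_overlapping` when the intervals
#' are disjoint. 5' and 3' ends are derived from the strand, so the rule
#' is symmetric in which transcript is called sense.
#'
#' @param senseLocus,antisenseLocus single-range
#'   [GenomicRanges::GRanges] on the same chromosome and opposite strands.
#' @return one of `"head_to_head"`, `"tail_to_tail"`,
#'   `"fully_overlapping"`, `"non_overlapping"`.
#' @export
#' @examples
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500), "+")
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 800), "-")
#' classifyOverlapCategory(s, a)   # tail_to_tail
classifyOverlapCategory <- function(senseLocus, antisenseLocus) {
  stopifnot(is(senseLocus, "GRanges"), is(antisenseLocus, "GRanges"),
            length(senseLocus) == 1L, length(antisenseLocus) == 1L)
  if (as.character(seqnames(senseLocus)) !=
        as.character(seqnames(antisenseLocus)))
    stop("loci must be on the same chromosome")
  st1 <- as.character(strand(senseLocus))
  st2 <- as.character(strand(antisenseLocus))
  if (!all(c(st1, st2) %in% c("+", "-")) || st1 == st2)
    stop("loci must be on opposite strands")
  s1 <- start(senseLocus);     e1 <- end(senseLocus)
  s2 <- start(antisenseLocus); e2 <- end(antisenseLocus)
  if (e1 < s2 || e2 < s1) return("non_overlapping")
  if ((s2 >= s1 && e2 <= e1) || (s1 >= s2 && e1 <= e2))
    return("fully_overlapping")
  five1  <- if (st1 == "+") s1 else e1
  five2  <- if (st2 == "+") s2 else e2
  ovS <- max(s1, s2); ovE <- min(e1, e2)
  inOv <- function(p) p >= ovS && p <= ovE
  if (inOv(five1) && inOv(five2)) "head_to_head" else "tail_to_tail"
}

#' Concordance label for a sense:antisense pair
#'
#' A pair is discordant when its sense and antisense mean intensities
#' differ by strictly more than `tau` on the log2 scale (default 1, i.e.
#' two-fold); an exactly two-fold difference is concordant. A fixed,
#' documented cutoff makes the qualitative similar-versus-differential
#' distinction testable.
#'
#' @param meanSense,meanAntisense positive mean linear intensities.
#' @param tau log2 discordance threshold, strict (default 1).
#' @return `"concordant"` or `"discordant"` (vectorised).
#' @export
labelConcordance <- function(meanSense, meanAntisense, tau = 1) {
  if (any(meanSense <= 0) || any(meanAntisense <= 0))
    stop("mean intensities must be positive")
  ifelse(abs(log2(meanSense) - log2(meanAntisense)) > tau,
         "discordant", "concordant")
}

#' Find sense:antisense pairs
#'
#' Pairs are the genes present in both deduplicated orientation sets. When
#' an annotation is supplied, each pair is given one representative
#' probeset per orientation — the probeset with the highest mean intensity
#' when intensities are available (favouring the measurable signal),
#' otherwise the alphabetically first. With transcript loci the cis-NAT
#' overlap category is recorded; with intensities the concordance label.
#'
#' @param senseGenes,antisenseGenes deduplicated gene-id sets (see
#'   [dedupeByGene()]).
#' @param annotation optional probeset annotation (`probeset_id`,
#'   `gene_id`, `orientation`).
#' @param meanIntensity optional named numeric, mean intensity per
#'   probeset.
#' @param loci optional named [GenomicRanges::GRanges] of transcript loci
#'   with a `gene_id` metadata column; used for overlap categories. The
#'   annotation must then carry `transcript_id`.
#' @param tau log2 concordance threshold passed to [labelConcordance()].
#' @return a [SASPairTable].
#' @export
findSASPairs <- function(senseGenes, antisenseGenes, annotation = NULL,
                         meanIntensity = NULL, loci = NULL, tau = 1) {
  genes <- sort(intersect(senseGenes, antisenseGenes))
  pickRep <- function(gene, ori) {
    if (is.null(annotation)) return(NA_character_)
    a <- as.data.frame(annotation)
    cand <- a$probeset_id[!is.na(a$gene_id) & a$gene_id == gene &
                            a$orientation == ori]
    if (!length(cand)) return(NA_character_)
    if (!is.null(meanIntensity) && all(cand %in% names(meanIntensity)))
      cand[order(-meanIntensity[cand], cand)][1L]
    else sort(cand)[1L]
  }
  sp <- vapply(genes, pickRep, character(1), ori = "sense")
  ap <- vapply(genes, pickRep, character(1), ori = "antisense")
  categ <- rep(NA_character_, length(genes))
  if (!is.null(loci) && !is.null(annotation) && length(genes)) {
    a <- as.data.frame(annotation)
    for (i in seq_along(genes)) {
      ts <- a$transcript_id[match(sp[i], a$probeset_id)]
      ta <- a$transcript_id[match(ap[i], a$probeset_id)]
      if (!is.na(ts) && !is.na(ta) && ts %in% names(loci) &&
            ta %in% names(loci))
        categ[i] <- classifyOverlapCategory(loci[ts], loci[ta])
    }
  }
  conc <- rep(NA_character_, length(genes))
  if (!is.null(meanIntensity) && length(genes)) {
    ok <- sp %in% names(meanIntensity) & ap %in% names(meanIntensity)
    if (any(ok))
      conc[ok] <- labelConcordance(meanIntensity[sp[ok]],
                                   meanIntensity[ap[ok]], tau = tau)
  }
  new("SASPairTable",
      pairs = DataFrame(gene_id = genes, sense_probeset = unname(sp),
                        antisense_probeset = unname(ap),
                        category = categ, concordance = conc),
      senseGenes = sort(unique(senseGenes)),
      antisenseGenes = sort(unique(antisenseGenes)))
}

#' Cross-experiment overlap of sense, antisense and SAS-pair gene sets
#'
#' Counts, for every pair of experiments, how many genes are shared per
#' class — sense, antisense, and SAS pairs — mirroring the summary of
#' shared content between in-vitro and clinical analyses.
#'
#' @param tables named list; each element a list with character elements
#'   `sense`, `antisense`, `pairs` (gene-id sets).
#' @return data.frame with columns `experiment_a`, `experiment_b`,
#'   `class`, `overlap`.
#' @export
#' @examples
#' crossExperimentOverlap(list(
#'   sensitive = list(sense = c("a", "b"), antisense = "a", pairs = "a"),
#'   clinical  = list(sense = "b", antisense = "a", pairs = character())))
crossExperimentOverlap <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L, !is.null(names(tables)))
  cls <- c("sense", "antisense", "pairs")
  nm <- names(tables)
  out <- list()
  for (i in seq_len(length(nm) - 1L)) for (j in seq((i + 1L), length(nm))) {
    for (cl in cls)
      out[[length(out) + 1L]] <- data.frame(
        experiment_a = nm[i], experiment_b = nm[j], class = cl,
        overlap = length(intersect(tables[[i]][[cl]], tables[[j]][[cl]])),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
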