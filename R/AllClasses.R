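#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Parameters of the synthetic transcriptome and array study
#'
#' Holds every tunable of the synthetic-data generator: the toy
#' transcriptome (gene count, natural-antisense frequency and overlap
#' geometry, transcript lengths), the two array designs (probe and probeset
#' geometry, shared content, per-gene probeset redundancy on the generic
#' platform, size of the unannotated stratum), and the expression model
#' (planted effect sizes, replicate noise, detection-call thresholds, flag
#' corruption, replicate and cohort sizes).
#'
#' Use the constructor [syntheticConfig()] rather than `new()`; it supplies
#' the study defaults and validates every field.
#'
#' @slot nGenes number of genes in the toy transcriptome.
#' @slot natFraction probability that a gene carries a natural antisense
#'   partner transcript on the opposite strand of the same locus.
#' @slot overlapWeights named probabilities over the cis-NAT overlap
#'   categories `head_to_head`, `tail_to_tail`, `fully_overlapping`.
#' @slot lengthRange two integers, the uniform range of sense transcript
#'   lengths in nucleotides.
#' @slot probeLength probe length in nucleotides (25 by default).
#' @slot probesPerProbeset probes per probeset (11 by default).
#' @slot sharedFraction fraction of genes represented on both platforms.
#' @slot redundancyGeneric mean probesets per gene on the generic platform.
#' @slot unassignedFraction target share of disease-specific probesets with
#'   no orientation annotation.
#' @slot deFraction fraction of transcripts with a planted treatment effect
#'   per comparison.
#' @slot effectLog2 magnitude of the planted log2 fold change.
#' @slot noiseSdLog2 replicate noise standard deviation on the log2 scale.
#' @slot baselineLog2Mean,baselineLog2Sd distribution of per-transcript
#'   baseline log2 intensities.
#' @slot detectP,detectM linear-intensity thresholds for Present and
#'   Marginal flag calls (`detectM < detectP`).
#' @slot flagFlipRate probability that a flag call is corrupted.
#' @slot nReps replicates per in-vitro condition.
#' @slot nClinical clinical cohort size.
#' @slot seed master seed; each generation stage derives its own stream.
#' @seealso [syntheticConfig()], [simulateStudy()]
#' @export
setClass("SyntheticConfig",
  representation(
    nGenes            = "integer",
    natFraction       = "numeric",
    overlapWeights    = "numeric",
    lengthRange       = "integer",
    probeLength       = "integer",
    probesPerProbeset = "integer",
    sharedFraction    = "numeric",
    redundancyGeneric = "numeric",
    unassignedFraction = "numeric",
    deFraction        = "numeric",
    effectLog2        = "numeric",
    noiseSdLog2       = "numeric",
    baselineLog2Mean  = "numeric",
    baselineLog2Sd    = "numeric",
    detectP           = "numeric",
    detectM           = "numeric",
    flagFlipRate      = "numeric",
    nReps             = "integer",
    nClinical         = "integer",
    seed              = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  fr <- c(natFraction = object@natFraction,
          sharedFraction = object@sharedFraction,
          unassignedFraction = object@unassignedFraction,
          deFraction = object@deFraction,
          flagFlipRate = object@flagFlipRate)
  bad <- names(fr)[is.na(fr) | fr < 0 | fr > 1]
  if (length(bad))
    msg <- c(msg, paste0("fractions must lie in [0, 1]: ",
                         paste(bad, collapse = ", ")))
  w <- object@overlapWeights
  if (length(w) != 3L ||
      !setequal(names(w), c("head_to_head", "tail_to_tail", "fully_overlapping")))
    msg <- c(msg, "overlapWeights must be named head_to_head, tail_to_tail, fully_overlapping")
  else if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "overlapWeights must be non-negative and sum to 1")
  if (length(object@lengthRange) != 2L || object@lengthRange[1] > object@lengthRange[2])
    msg <- c(msg, "lengthRange must be an increasing pair of lengths")
  if (object@probeLength > min(object@lengthRange))
    msg <- c(msg, "probeLength exceeds the minimum transcript length")
  if (object@detectM >= object@detectP)
    msg <- c(msg, "detectM must be strictly below detectP")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@redundancyGeneric < 1)
    msg <- c(msg, "redundancyGeneric must be >= 1")
  if (object@noiseSdLog2 < 0 || object@baselineLog2Sd < 0)
    msg <- c(msg, "noise and baseline standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A toy transcriptome: loci plus sequences
#'
#' Transcript records produced by [generateTranscriptome()]: genomic loci as
#' a [GenomicRanges::GRanges] (names are transcript ids; metadata columns
#' `gene_id` and `orientation`) and the matching transcript sequences as a
#' [Biostrings::DNAStringSet]. Antisense transcripts share their partner's
#' `gene_id`, lie on the opposite strand, and overlap it genomically; their
#' sequences are derived from the same genomic sequence, so probe matching
#' across orientations behaves as it would on a real locus.
#'
#' @slot loci `GRanges` of transcript loci.
#' @slot seqs `DNAStringSet` of transcript sequences, parallel to `loci`.
#' @seealso [generateTranscriptome()], [transcriptLoci()], [transcriptSeqs()]
#' @export
setClass("Transcriptome",
  representation(loci = "GRanges", seqs = "DNAStringSet"))

setValidity("Transcriptome", function(object) {
  msg <- character()
  if (length(object@loci) != length(object@seqs))
    msg <- c(msg, "loci and seqs must have equal length")
  if (!identical(names(object@loci), names(object@seqs)))
    msg <- c(msg, "loci and seqs must carry identical transcript ids")
  mc <- names(S4Vectors::mcols(object@loci))
  if (!all(c("gene_id", "orientation") %in% mc))
    msg <- c(msg, "loci must carry gene_id and orientation metadata columns")
  if (length(object@loci) &&
      !all(S4Vectors::mcols(object@loci)$orientation %in%
             c("sense", "antisense", "unassigned")))
    msg <- c(msg, "orientation must be sense, antisense or unassigned")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' Machine-readable record of what the generator planted, used by the test
#' suite to verify that the analysis modules recover it: the probesets whose
#' source sequences are genuinely present on both platforms (derived from
#' locus geometry, independently of any sequence matching), the transcripts
#' with planted differential expression per comparison, the genes carrying
#' both orientations on the disease-specific platform, and each
#' antisense-bearing gene's overlap category.
#'
#' @slot commonProbesets character, probeset ids (both platforms) truly
#'   backed by shared sequence content.
#' @slot plantedDE named list; per comparison a data.frame of planted
#'   transcript effects (`transcript_id`, `sign`, and for the clinical
#'   cohort the affected response `group`).
#' @slot plantedSASGenes character, gene ids with both orientations on the
#'   disease-specific platform.
#' @slot categoryByGene named character, overlap category per
#'   antisense-bearing gene.
#' @export
setClass("GroundTruth",
  representation(
    commonProbesets = "character",
    plantedDE       = "list",
    plantedSASGenes = "character",
    categoryByGene  = "character"
  )
)

setValidity("GroundTruth", function(object) {
  if (length(object@plantedSASGenes) &&
      !all(object@plantedSASGenes %in% names(object@categoryByGene)))
    return("plantedSASGenes must be a subset of antisense-bearing genes")
  TRUE
})

#' A microarray platform design
#'
#' One platform's probe content: every probe sequence (names follow the
#' pattern `<probeset_id>_p<nn>`), the probeset annotation (probeset id,
#' source transcript, gene id, orientation), and the full-length sequence of
#' every transcript represented on the platform. Probes are verbatim
#' substrings of their source transcript.
#'
#' @slot platformName label of the platform (e.g. `"generic"`, `"dsa"`).
#' @slot probes `DNAStringSet` of probe sequences.
#' @slot annotation `DataFrame` with columns `probeset_id`, `transcript_id`,
#'   `gene_id`, `orientation`.
#' @slot fullLength `DNAStringSet` of full-length transcript sequences,
#'   named by transcript id.
#' @seealso [designPlatforms()], [probes()], [probesetAnnotation()],
#'   [fullLengthSeqs()]
#' @export
setClass("PlatformDesign",
  representation(
    platformName = "character",
    probes       = "DNAStringSet",
    annotation   = "DataFrame",
    fullLength   = "DNAStringSet"
  )
)

setValidity("PlatformDesign", function(object) {
  msg <- character()
  need <- c("probeset_id", "transcript_id", "gene_id", "orientation")
  if (!all(need %in% colnames(object@annotation)))
    msg <- c(msg, paste0("annotation must have columns ",
                         paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@annotation$probeset_id))
      msg <- c(msg, "probeset ids must be unique")
    if (length(object@probes)) {
      ps <- sub("_p[0-9]+$", "", names(object@probes))
      if (!all(ps %in% object@annotation$probeset_id))
        msg <- c(msg, "every probe must belong to an annotated probeset")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Exact-match index over a sequence set
#'
#' Supports exact lookup of fixed-length words against a set of target
#' sequences on both strands: the forward strand is the sequences as given,
#' the reverse strand their reverse complements. Built by
#' [indexSequences()]; queried by [queryIndex()] and [matchProbeset()].
#'
#' @slot subject `DNAStringSet`, the target sequences (forward strand).
#' @slot rcSubject `DNAStringSet`, their reverse complements.
#' @export
setClass("ProbeIndex",
  representation(subject = "DNAStringSet", rcSubject = "DNAStringSet"))

setValidity("ProbeIndex", function(object) {
  if (length(object@subject) == 0L)
    return("cannot index an empty sequence set")
  if (is.null(names(object@subject)))
    return("indexed sequences must be named")
  if (!identical(names(object@subject), names(object@rcSubject)))
    return("subject and rcSubject must be parallel")
  TRUE
})

#' Common/unique partition of two platforms' probesets
#'
#' Result of the bidirectional exact-matching classification
#' ([classifyCommonUnique()]): per probeset its platform, class (`common` or
#' `unique`), best-matching full-length sequence on the other platform, the
#' number of probes matching that sequence, and the strand carrying the
#' match. Probesets without a full-length sequence record are excluded from
#' the partition and reported in `excluded`.
#'
#' @slot table `DataFrame` with columns `probeset_id`, `platform`, `class`,
#'   `best_target`, `n_matched`, `strand`.
#' @slot platforms character of length 2, the platform labels.
#' @slot minProbes the probes-per-sequence threshold used.
#' @slot excluded character, probeset ids excluded for lack of a sequence
#'   record.
#' @seealso [commonProbesets()], [uniqueProbesets()], [partitionSummary()]
#' @export
setClass("ContentPartition",
  representation(
    table     = "DataFrame",
    platforms = "character",
    minProbes = "integer",
    excluded  = "character"
  )
)

setValidity("ContentPartition", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("probeset_id", "platform", "class", "best_target", "n_matched", "strand")
  if (!all(need %in% colnames(tab)))
    msg <- c(msg, paste0("table must have columns ", paste(need, collapse = ", ")))
  else {
    if (!all(tab$class %in% c("common", "unique")))
      msg <- c(msg, "class must be 'common' or 'unique'")
    if (!all(tab$platform %in% object@platforms))
      msg <- c(msg, "platform labels must match the platforms slot")
    if (anyDuplicated(tab$probeset_id))
      msg <- c(msg, "a probeset may appear only once in the partition")
  }
  if (length(msg)) msg else TRUE
})

#' Expression matrix with MAS5-style flag calls
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying two parallel
#' assays — `exprs`, linear-scale expression intensities, and `flags`,
#' Present/Marginal/Absent detection calls — plus a design in `colData`:
#' either replicated in-vitro conditions (`condition`, `replicate`) or a
#' clinical cohort (`response` in CR/PR/SD/PD).
#'
#' @seealso [FlaggedExperiment()], [flagCalls()], [intensities()]
#' @export
setClass("FlaggedExperiment", contains = "SummarizedExperiment")

setValidity("FlaggedExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("exprs", "flags") %in% an))
    return("assays 'exprs' and 'flags' are required")
  e <- SummarizedExperiment::assay(object, "exprs")
  f <- SummarizedExperiment::assay(object, "flags")
  if (!all(f %in% c("P", "M", "A")))
    msg <- c(msg, "flags must be 'P', 'M' or 'A'")
  if (any(!is.finite(e)) || any(e <= 0))
    msg <- c(msg, "intensities must be positive and finite")
  cd <- colnames(SummarizedExperiment::colData(object))
  invitro  <- all(c("condition", "replicate") %in% cd)
  clinical <- "response" %in% cd
  if (!invitro && !clinical)
    msg <- c(msg, "colData must describe conditions/replicates or clinical response")
  if (clinical && !invitro) {
    resp <- SummarizedExperiment::colData(object)$response
    if (!all(resp %in% c("CR", "PR", "SD", "PD")))
      msg <- c(msg, "clinical response labels must be CR, PR, SD or PD")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a detection + differential-expression filter cascade
#'
#' The detected probeset set for a comparison together with the nested
#' differentially expressed subset and per-probeset statistics (fold change
#' with direction, p value, degenerate-variance flag).
#'
#' @slot comparison label of the comparison (e.g. `"sensitive"`).
#' @slot detected character, probesets passing the detection filter in the
#'   compared conditions.
#' @slot stats `DataFrame` of per-probeset statistics over `detected`.
#' @slot de character, probesets passing the full cascade (a subset of
#'   `detected`).
#' @slot params list echoing the filter settings.
#' @seealso [deFilter()], [deFilterClinical()], [detectedProbesets()],
#'   [deProbesets()], [deStats()]
#' @export
setClass("FilterCascadeResult",
  representation(
    comparison = "character",
    detected   = "character",
    stats      = "DataFrame",
    de         = "character",
    params     = "list"
  )
)

setValidity("FilterCascadeResult", function(object) {
  msg <- character()
  if (!all(object@de %in% object@detected))
    msg <- c(msg, "differentially expressed probesets must be a subset of detected")
  if (nrow(object@stats) &&
      !all(object@stats$probeset_id %in% object@detected))
    msg <- c(msg, "statistics rows must refer to detected probesets")
  if (length(msg)) msg else TRUE
})

#' Sense:antisense pair table
#'
#' Gene-level sense/antisense membership and the matched pairs: genes
#' represented in both orientations, each with one representative probeset
#' per orientation, the cis-NAT overlap category when loci are available,
#' and a concordant/discordant expression label when intensities are
#' available.
#'
#' @slot pairs `DataFrame` with columns `gene_id`, `sense_probeset`,
#'   `antisense_probeset`, `category`, `concordance`.
#' @slot senseGenes character, deduplicated genes with sense probesets.
#' @slot antisenseGenes character, deduplicated genes with antisense
#'   probesets.
#' @seealso [findSASPairs()], [sasPairs()], [pairedGenes()]
#' @export
setClass("SASPairTable",
  representation(
    pairs          = "DataFrame",
    senseGenes     = "character",
    antisenseGenes = "character"
  )
)

setValidity("SASPairTable", function(object) {
  msg <- character()
  p <- object@pairs$gene_id
  if (length(p) > min(length(object@senseGenes), length(object@antisenseGenes)))
    msg <- c(msg, "cannot have more pairs than genes in either orientation")
  if (!all(p %in% object@senseGenes) || !all(p %in% object@antisenseGenes))
    msg <- c(msg, "paired genes must occur in both orientation sets")
  if (anyDuplicated(p)) msg <- c(msg, "one pair per gene")
  if (length(msg)) msg else TRUE
})
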