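#' @include AllGenerics.R
NULL

#' @rdname Transcriptome-class
#' @aliases transcriptLoci,Transcriptome-method
setMethod("transcriptLoci", "Transcriptome", function(x) x@loci)

#' @rdname Transcriptome-class
#' @aliases transcriptSeqs,Transcriptome-method
setMethod("transcriptSeqs", "Transcriptome", function(x) x@seqs)

setMethod("show", "Transcriptome", function(object) {
  ori <- table(factor(S4Vectors::mcols(object@loci)$orientation,
                      levels = c("sense", "antisense", "unassigned")))
  cat("Transcriptome with", length(object@loci), "transcripts\n")
  cat("  sense:", ori[["sense"]], " antisense:", ori[["antisense"]],
      " unassigned:", ori[["unassigned"]], "\n")
  cat("  genes:", length(unique(stats::na.omit(
    S4Vectors::mcols(object@loci)$gene_id))), "\n")
})

#' @rdname PlatformDesign-class
#' @aliases probes,PlatformDesign-method
setMethod("probes", "PlatformDesign", function(x) x@probes)

#' @rdname PlatformDesign-class
#' @aliases probesetAnnotation,PlatformDesign-method
setMethod("probesetAnnotation", "PlatformDesign", function(x) x@annotation)

#' @rdname PlatformDesign-class
#' @aliases fullLengthSeqs,PlatformDesign-method
setMethod("fullLengthSeqs", "PlatformDesign", function(x) x@fullLength)

#' @rdname PlatformDesign-class
#' @aliases platformName,PlatformDesign-method
setMethod("platformName", "PlatformDesign", function(x) x@platformName)

setMethod("show", "PlatformDesign", function(object) {
  anno <- object@annotation
  cat("PlatformDesign '", object@platformName, "': ",
      nrow(anno), " probesets, ", length(object@probes), " probes, ",
      length(object@fullLength), " full-length sequences\n", sep = "")
  ori <- table(factor(anno$orientation,
                      levels = c("sense", "antisense", "unassigned")))
  cat("  orientation  sense:", ori[["sense"]], " antisense:", ori[["antisense"]],
      " unassigned:", ori[["unassigned"]], "\n")
})

#' @rdname commonProbesets
#' @aliases commonProbesets,ContentPartition-method
#' @param platform optional platform label.
setMethod("commonProbesets", "ContentPartition", function(x, platform = NULL) {
  tab <- x@table
  keep <- tab$class == "common"
  if (!is.null(platform)) {
    if (!platform %in% x@platforms)
      stop("unknown platform: ", platform)
    keep <- keep & tab$platform == platform
  }
  tab$probeset_id[keep]
})

#' @rdname commonProbesets
#' @aliases uniqueProbesets,ContentPartition-method
setMethod("uniqueProbesets", "ContentPartition", function(x, platform = NULL) {
  tab <- x@table
  keep <- tab$class == "unique"
  if (!is.null(platform)) {
    if (!platform %in% x@platforms)
      stop("unknown platform: ", platform)
    keep <- keep & tab$platform == platform
  }
  tab$probeset_id[keep]
})

#' @rdname commonProbesets
#' @aliases commonProbesets,GroundTruth-method
setMethod("commonProbesets", "GroundTruth", function(x) x@commonProbesets)

#' @rdname ContentPartition-class
#' @aliases partitionTable,ContentPartition-method
setMethod("partitionTable", "ContentPartition", function(x) x@table)

#' @rdname ContentPartition-class
#' @aliases partitionSummary,ContentPartition-method
setMethod("partitionSummary", "ContentPartition", function(x) {
  tab <- x@table
  m <- sapply(x@platforms, function(p) {
    on <- tab$platform == p
    c(Total  = sum(on),
      Common = sum(on & tab$class == "common"),
      Unique = sum(on & tab$class == "unique"))
  })
  t(m)
})

setMethod("show", "ContentPartition", function(object) {
  cat("ContentPartition (>=", object@minProbes,
      "probes on one sequence, both strands)\n")
  print(partitionSummary(object))
  if (length(object@excluded))
    cat("  excluded (no sequence record):", length(object@excluded), "\n")
})

#' @rdname FlaggedExperiment-class
#' @aliases flagCalls,FlaggedExperiment-method
setMethod("flagCalls", "FlaggedExperiment", function(x)
  SummarizedExperiment::assay(x, "flags"))

#' @rdname FlaggedExperiment-class
#' @aliases intensities,FlaggedExperiment-method
setMethod("intensities", "FlaggedExperiment", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname FilterCascadeResult-class
#' @aliases detectedProbesets,FilterCascadeResult-method
setMethod("detectedProbesets", "FilterCascadeResult", function(x) x@detected)

#' @rdname FilterCascadeResult-class
#' @aliases deProbesets,FilterCascadeResult-method
setMethod("deProbesets", "FilterCascadeResult", function(x) x@de)

#' @rdname FilterCascadeResult-class
#' @aliases deStats,FilterCascadeResult-method
setMethod("deStats", "FilterCascadeResult", function(x) x@stats)

setMethod("show", "FilterCascadeResult", function(object) {
  cat("FilterCascadeResult '", object@comparison, "'\n", sep = "")
  cat("  detected:", length(object@detected),
      "  differentially expressed:", length(object@de), "\n")
  p <- object@params
  if (length(p))
    cat("  settings: fold >=", p$foldThreshold,
        if (!is.null(p$pThreshold)) paste0(", p < ", p$pThreshold), "\n")
})

#' @rdname SASPairTable-class
#' @aliases sasPairs,SASPairTable-method
setMethod("sasPairs", "SASPairTable", function(x) x@pairs)

#' @rdname SASPairTable-class
#' @aliases pairedGenes,SASPairTable-method
setMethod("pairedGenes", "SASPairTable", function(x) x@pairs$gene_id)

setMethod("show", "SASPairTable", function(object) {
  cat("SASPairTable: ", length(object@senseGenes), " sense genes, ",
      length(object@antisenseGenes), " antisense genes, ",
      nrow(object@pairs), " SAS pairs\n", sep = "")
})
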