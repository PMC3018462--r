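#' @include AllClasses.R
NULL

#' @rdname Transcriptome-class
#' @param x a `Transcriptome`.
#' @export
setGeneric("transcriptLoci", function(x) standardGeneric("transcriptLoci"))

#' @rdname Transcriptome-class
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))

#' @rdname PlatformDesign-class
#' @param x a `PlatformDesign`.
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname PlatformDesign-class
#' @export
setGeneric("probesetAnnotation", function(x) standardGeneric("probesetAnnotation"))

#' @rdname PlatformDesign-class
#' @export
setGeneric("fullLengthSeqs", function(x) standardGeneric("fullLengthSeqs"))

#' @rdname PlatformDesign-class
#' @export
setGeneric("platformName", function(x) standardGeneric("platformName"))

#' Common and unique probeset accessors
#'
#' Extract the common (shared-content) or unique probeset ids from a
#' [ContentPartition] (optionally restricted to one platform) or the true
#' common set from a [GroundTruth].
#'
#' @param x a `ContentPartition` or `GroundTruth`.
#' @param ... for `ContentPartition`, optionally `platform`, a platform
#'   label restricting the result.
#' @return character vector of probeset ids.
#' @export
setGeneric("commonProbesets", function(x, ...) standardGeneric("commonProbesets"))

#' @rdname commonProbesets
#' @export
setGeneric("uniqueProbesets", function(x, ...) standardGeneric("uniqueProbesets"))

#' @rdname ContentPartition-class
#' @param x a `ContentPartition`.
#' @export
setGeneric("partitionTable", function(x) standardGeneric("partitionTable"))

#' @rdname ContentPartition-class
#' @export
setGeneric("partitionSummary", function(x) standardGeneric("partitionSummary"))

#' @rdname FlaggedExperiment-class
#' @param x a `FlaggedExperiment`.
#' @export
setGeneric("flagCalls", function(x) standardGeneric("flagCalls"))

#' @rdname FlaggedExperiment-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname FilterCascadeResult-class
#' @param x a `FilterCascadeResult`.
#' @export
setGeneric("detectedProbesets", function(x) standardGeneric("detectedProbesets"))

#' @rdname FilterCascadeResult-class
#' @export
setGeneric("deProbesets", function(x) standardGeneric("deProbesets"))

#' @rdname FilterCascadeResult-class
#' @export
setGeneric("deStats", function(x) standardGeneric("deStats"))

#' @rdname SASPairTable-class
#' @param x a `SASPairTable`.
#' @export
setGeneric("sasPairs", function(x) standardGeneric("sasPairs"))

#' @rdname SASPairTable-class
#' @export
setGeneric("pairedGenes", function(x) standardGeneric("pairedGenes"))
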