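#' @include AllClasses.R
NULL

.writeTSV <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

.readTSV <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write and read a platform design
#'
#' A platform is laid out as a directory holding `probes.fasta` (headers
#' are probe names, `<probeset_id>_p<nn>`), `fulllength.fasta` (headers
#' are transcript ids) and `annotation.tsv` (`probeset_id`,
#' `transcript_id`, `gene_id`, `orientation`).
#'
#' @param platform a [PlatformDesign].
#' @param dir directory to write to (created if needed).
#' @return `writePlatformDesign()` returns the directory invisibly;
#'   `readPlatformDesign()` returns a [PlatformDesign].
#' @export
writePlatformDesign <- function(platform, dir) {
  stopifnot(is(platform, "PlatformDesign"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(platform@probes, file.path(dir, "probes.fasta"))
  writeXStringSet(platform@fullLength, file.path(dir, "fulllength.fasta"))
  .writeTSV(platform@annotation, file.path(dir, "annotation.tsv"))
  invisible(dir)
}

#' @rdname writePlatformDesign
#' @param platformName label for the platform read back.
#' @export
readPlatformDesign <- function(dir, platformName = basename(dir)) {
  anno <- .readTSV(file.path(dir, "annotation.tsv"))
  new("PlatformDesign", platformName = platformName,
      probes = readDNAStringSet(file.path(dir, "probes.fasta")),
      annotation = DataFrame(anno),
      fullLength = readDNAStringSet(file.path(dir, "fulllength.fasta")))
}

#' Write and read an expression experiment
#'
#' An experiment is a directory holding `expression.tsv` and `flags.tsv`
#' (probesets x samples, first column `probeset_id`, header row = sample
#' ids) plus `design.tsv`.
#'
#' @param x a [FlaggedExperiment].
#' @param dir directory to write to.
#' @return `writeFlaggedExperiment()` returns the directory invisibly;
#'   `readFlaggedExperiment()` returns a [FlaggedExperiment].
#' @export
writeFlaggedExperiment <- function(x, dir) {
  stopifnot(is(x, "FlaggedExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  e <- data.frame(probeset_id = rownames(x), intensities(x),
                  check.names = FALSE)
  f <- data.frame(probeset_id = rownames(x), flagCalls(x),
                  check.names = FALSE)
  .writeTSV(e, file.path(dir, "expression.tsv"))
  .writeTSV(f, file.path(dir, "flags.tsv"))
  d <- as.data.frame(SummarizedExperiment::colData(x))
  d <- cbind(sample_id = rownames(d), d)
  rownames(d) <- NULL
  .writeTSV(d, file.path(dir, "design.tsv"))
  invisible(dir)
}

#' @rdname writeFlaggedExperiment
#' @export
readFlaggedExperiment <- function(dir) {
  e <- .readTSV(file.path(dir, "expression.tsv"))
  f <- .readTSV(file.path(dir, "flags.tsv"))
  d <- .readTSV(file.path(dir, "design.tsv"))
  em <- as.matrix(e[, -1, drop = FALSE])
  fm <- as.matrix(f[, -1, drop = FALSE])
  rownames(em) <- e$probeset_id
  rownames(fm) <- f$probeset_id
  colnames(em) <- colnames(fm) <- d$sample_id
  FlaggedExperiment(em, fm, d)
}

#' Write and read the planted ground truth
#'
#' Serialises a [GroundTruth] to JSON so that synthetic datasets stay
#' self-describing on disk.
#'
#' @param truth a [GroundTruth].
#' @param path JSON file path.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(
    list(common_probesets = truth@commonProbesets,
         planted_de = truth@plantedDE,
         planted_sas_genes = truth@plantedSASGenes,
         category_by_gene = as.list(truth@categoryByGene)),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pde <- lapply(j$planted_de, function(d) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    if (!nrow(d)) {
      d <- data.frame(transcript_id = character(), sign = numeric(),
                      stringsAsFactors = FALSE)
    }
    d
  })
  new("GroundTruth",
      commonProbesets = as.character(j$common_probesets),
      plantedDE = pde,
      plantedSASGenes = as.character(j$planted_sas_genes),
      categoryByGene = unlist(j$category_by_gene))
}

#' Write transcript loci as BED6
#'
#' Exports transcript loci (name = transcript id, score 0, strand kept) in
#' BED format; BED's 0-based half-open convention is handled by the
#' exporter.
#'
#' @param transcriptome a [Transcriptome] (or a named `GRanges`).
#' @param path BED file path.
#' @export
writeTranscriptLoci <- function(transcriptome, path) {
  gr <- if (is(transcriptome, "Transcriptome")) transcriptome@loci
        else transcriptome
  S4Vectors::mcols(gr)$name <- names(gr)
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeTranscriptLoci
#' @return `readTranscriptLoci()` returns a named `GRanges`.
#' @export
readTranscriptLoci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  names(gr) <- S4Vectors::mcols(gr)$name
  gr
}

#' Read and write GMT gene-set files
#'
#' `readGMT()` parses a GMT pathway file into a named list of gene-id
#' vectors; `writeGMT()` writes one (the description field is left empty).
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGMT
#' @param pathways named list of gene-id character vectors.
#' @export
writeGMT <- function(pathways, path) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "", pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a content partition
#'
#' Writes `partition.tsv` (one row per probeset: id, platform, class, best
#' target, probes matched, strand) and `content_summary.tsv`, a
#' total/common/unique count table per platform.
#'
#' @param partition a [ContentPartition].
#' @param dir directory to write to.
#' @export
writePartition <- function(partition, dir) {
  stopifnot(is(partition, "ContentPartition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .writeTSV(partition@table, file.path(dir, "partition.tsv"))
  sm <- partitionSummary(partition)
  .writeTSV(data.frame(platform = rownames(sm), sm, check.names = FALSE),
            file.path(dir, "content_summary.tsv"))
  invisible(dir)
}
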