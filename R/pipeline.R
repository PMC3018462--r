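#' @include AllClasses.R
NULL

#' Render a count as a percentage string
#'
#' `100 * count / total`, half-up rounded to `decimals` places and
#' rendered with a percent sign — the rounding convention used in every
#' summary table this package writes.
#'
#' @param count,total non-negative counts, `count <= total`, `total > 0`.
#' @param decimals decimal places (default 2).
#' @return character, e.g. `"42.25%"`.
#' @export
#' @examples
#' percentBreakdown(9754, 23089)
percentBreakdown <- function(count, total, decimals = 2L) {
  if (!is.numeric(count) || !is.numeric(total) || any(total <= 0))
    stop("total must be positive")
  if (any(count < 0) || any(count > total))
    stop("count must lie in [0, total]")
  paste0(formatC(roundHalfUp(100 * count / total, decimals),
                 format = "f", digits = decimals), "%")
}

# gene-level sense/antisense/pair sets for one probeset subset
.sasGeneSets <- function(annotation, probesetIds) {
  list(sense = dedupeByGene(annotation, "sense", probesetIds),
       antisense = dedupeByGene(annotation, "antisense", probesetIds),
       pairs = intersect(dedupeByGene(annotation, "sense", probesetIds),
                         dedupeByGene(annotation, "antisense", probesetIds)))
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a study, writes every input (platform FASTA/annotation,
#' expression/flag/design tables, transcript loci BED, ground-truth JSON),
#' then runs every analysis stage — content mapping, detection and
#' differential-expression cascades for the sensitive, resistant and
#' clinical experiments, pathway over-representation, sense:antisense
#' discovery on the disease-specific unique content, and array-versus-qPCR
#' concordance on a synthetic validation panel — writing a paper-style
#' table for each stage plus a manifest with a content digest of every
#' file. Rerunning with the same configuration reproduces the bundle
#' byte for byte.
#'
#' The pathway-count cutoffs default to values scaled to the synthetic
#' experiment size (the full-scale rule — strictly more than 15 or 10
#' genes per pathway — is itself chosen relative to the number of genes in
#' the experiment).
#'
#' @param config a [SyntheticConfig].
#' @param outDir output directory (created).
#' @param minProbes probes-per-sequence threshold for content mapping.
#' @param foldInvitro,pThreshold in-vitro cascade settings.
#' @param foldClinical clinical cascade fold threshold.
#' @param minGenesSensitive,minGenesResistant strict pathway DE-gene-count
#'   cutoffs for the two in-vitro experiments.
#' @param alpha significance level for enrichment flags.
#' @param tau log2 concordance threshold for SAS pairs.
#' @param nQpcrGenes validation panel size for synthetic qPCR.
#' @param qpcrNoiseSd log2-scale noise between array and synthetic qPCR
#'   fold changes.
#' @param includeClinical run the clinical arm (default `TRUE`).
#' @return invisibly, a list with every intermediate result (`study`,
#'   `partition`, `filters`, `enrichment`, `sas`, `concordance`,
#'   `manifest`).
#' @export
runFullPipeline <- function(config = syntheticConfig(), outDir,
                            minProbes = 6L,
                            foldInvitro = 1.3, pThreshold = 0.05,
                            foldClinical = 1.5,
                            minGenesSensitive = 5L, minGenesResistant = 3L,
                            alpha = 0.05, tau = 1,
                            nQpcrGenes = 13L, qpcrNoiseSd = 0.35,
                            includeClinical = TRUE) {
  stopifnot(is(config, "SyntheticConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ## stage: simulate + write inputs
  study <- simulateStudy(config)
  writePlatformDesign(study$generic, file.path(outDir, "generic"))
  writePlatformDesign(study$dsa, file.path(outDir, "dsa"))
  writeFlaggedExperiment(study$invitroDsa, file.path(outDir, "invitro_dsa"))
  writeFlaggedExperiment(study$invitroGeneric,
                         file.path(outDir, "invitro_generic"))
  if (includeClinical)
    writeFlaggedExperiment(study$clinical, file.path(outDir, "clinical"))
  writeGroundTruth(study$truth, file.path(outDir, "truth.json"))
  writeTranscriptLoci(study$transcriptome, file.path(outDir, "loci.bed"))

  ## stage: content mapping
  partition <- classifyCommonUnique(study$generic, study$dsa,
                                    minProbes = minProbes)
  writePartition(partition, outDir)

  ## stage: filter cascades
  filters <- list(
    sensitive = deFilter(study$invitroDsa, "parental_untreated",
                         "parental_5FU", foldInvitro, pThreshold,
                         comparison = "sensitive"),
    resistant = deFilter(study$invitroDsa, "resistant_untreated",
                         "resistant_5FU", foldInvitro, pThreshold,
                         comparison = "resistant"),
    sensitive_generic = deFilter(study$invitroGeneric, "parental_untreated",
                                 "parental_5FU", foldInvitro, pThreshold,
                                 comparison = "sensitive_generic"),
    resistant_generic = deFilter(study$invitroGeneric, "resistant_untreated",
                                 "resistant_5FU", foldInvitro, pThreshold,
                                 comparison = "resistant_generic"))
  if (includeClinical)
    filters$clinical <- deFilterClinical(study$clinical, foldClinical)
  for (nm in names(filters)) {
    fr <- filters[[nm]]
    writeLines(detectedProbesets(fr),
               file.path(outDir, paste0("detected_", nm, ".txt")))
    .writeTSV(cbind(comparison = nm, as.data.frame(deStats(fr))),
              file.path(outDir, paste0("de_table_", nm, ".tsv")))
  }
  counts <- data.frame(
    comparison = names(filters),
    detected = vapply(filters, function(f) length(detectedProbesets(f)),
                      integer(1)),
    de = vapply(filters, function(f) length(deProbesets(f)), integer(1)))
  .writeTSV(counts, file.path(outDir, "filter_counts.tsv"))

  ## stage: pathway enrichment (disease-specific platform)
  dsaAnno <- probesetAnnotation(study$dsa)
  universe <- collapseToGenes(dsaAnno$probeset_id, dsaAnno)
  set.seed(.stageSeed(config@seed, 4L))
  plantedGenes <- intersect(
    dsaAnno$gene_id[dsaAnno$transcript_id %in%
                      study$truth@plantedDE$sensitive$transcript_id],
    universe)
  pathways <- makeSyntheticPathways(universe,
                                    plantedGenes = plantedGenes)
  writeGMT(pathways, file.path(outDir, "pathways.gmt"))
  enrichment <- list(
    sensitive = enrichPathways(
      intersect(collapseToGenes(deProbesets(filters$sensitive), dsaAnno),
                universe),
      universe, pathways, minGenes = minGenesSensitive, alpha = alpha),
    resistant = enrichPathways(
      intersect(collapseToGenes(deProbesets(filters$resistant), dsaAnno),
                universe),
      universe, pathways, minGenes = minGenesResistant, alpha = alpha))
  for (nm in names(enrichment))
    .writeTSV(enrichment[[nm]],
              file.path(outDir, paste0("enrichment_", nm, ".tsv")))

  ## stage: sense:antisense discovery on the disease-specific unique content
  dsaUnique <- uniqueProbesets(partition, "dsa")
  strata <- list(all = dsaUnique,
                 sensitive_detected = intersect(
                   dsaUnique, detectedProbesets(filters$sensitive)),
                 sensitive_de = intersect(dsaUnique,
                                          deProbesets(filters$sensitive)),
                 resistant_detected = intersect(
                   dsaUnique, detectedProbesets(filters$resistant)),
                 resistant_de = intersect(dsaUnique,
                                          deProbesets(filters$resistant)))
  if (includeClinical) {
    strata$clinical_detected <- intersect(
      dsaUnique, detectedProbesets(filters$clinical))
    strata$clinical_de <- intersect(dsaUnique,
                                    deProbesets(filters$clinical))
  }
  ob <- do.call(rbind, lapply(names(strata), function(nm) {
    if (!length(strata[[nm]])) return(NULL)   # nothing survived the filter
    cbind(stratum = nm, orientationBreakdown(dsaAnno, strata[[nm]]))
  }))
  .writeTSV(ob, file.path(outDir, "orientation_breakdown.tsv"))

  meanInt <- rowMeans(intensities(study$invitroDsa))
  loci <- transcriptLoci(study$transcriptome)
  sasTables <- lapply(strata, function(ids) {
    findSASPairs(dedupeByGene(dsaAnno, "sense", ids),
                 dedupeByGene(dsaAnno, "antisense", ids),
                 annotation = dsaAnno, meanIntensity = meanInt,
                 loci = loci, tau = tau)
  })
  sasOut <- do.call(rbind, lapply(names(sasTables), function(nm) {
    p <- as.data.frame(sasPairs(sasTables[[nm]]))
    if (!nrow(p)) return(NULL)
    cbind(stratum = nm, p)
  }))
  if (is.null(sasOut))
    sasOut <- data.frame(stratum = character(), gene_id = character())
  .writeTSV(sasOut, file.path(outDir, "sas_pairs.tsv"))
  sasCounts <- data.frame(
    stratum = names(sasTables),
    sense_genes = vapply(sasTables, function(t) length(t@senseGenes),
                         integer(1)),
    antisense_genes = vapply(sasTables, function(t)
      length(t@antisenseGenes), integer(1)),
    sas_pairs = vapply(sasTables, function(t) nrow(sasPairs(t)),
                       integer(1)))
  .writeTSV(sasCounts, file.path(outDir, "sas_counts.tsv"))

  overlapSets <- list(
    sensitive = .sasGeneSets(dsaAnno, strata$sensitive_detected),
    resistant = .sasGeneSets(dsaAnno, strata$resistant_detected))
  if (includeClinical)
    overlapSets$clinical <- .sasGeneSets(dsaAnno, strata$clinical_detected)
  overlap <- crossExperimentOverlap(overlapSets)
  .writeTSV(overlap, file.path(outDir, "overlap_matrix.tsv"))

  ## stage: synthetic qPCR concordance on the sensitive experiment
  set.seed(.stageSeed(config@seed, 5L))
  st <- as.data.frame(deStats(filters$sensitive))
  st <- st[order(-st$fold_change, st$probeset_id), , drop = FALSE]
  st <- st[st$passed, , drop = FALSE]
  concordance <- NULL
  if (nrow(st) >= 3L) {
    panel <- head(st, nQpcrGenes)
    sgn <- ifelse(panel$direction == "up", 1, -1)
    arrayLog <- sgn * log2(panel$fold_change)
    qpcrLog <- arrayLog + rnorm(nrow(panel), 0, qpcrNoiseSd)
    pairsDf <- data.frame(
      probeset_id = panel$probeset_id,
      array_fold = sign(arrayLog) * 2^abs(arrayLog),
      qpcr_fold = sign(qpcrLog) * 2^abs(qpcrLog))
    .writeTSV(pairsDf, file.path(outDir, "qpcr_pairs.tsv"))
    concordance <- concordanceFromFolds(pairsDf)
    jsonlite::write_json(concordance, file.path(outDir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  runInfo <- list(package = "SASpipe",
                  version = as.character(utils::packageVersion("SASpipe")),
                  seed = config@seed,
                  n_genes = config@nGenes,
                  min_probes = minProbes,
                  fold_invitro = foldInvitro,
                  fold_clinical = foldClinical,
                  p_threshold = pThreshold)
  jsonlite::write_json(runInfo, file.path(outDir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## manifest: every emitted file with a content digest
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outDir, files))))
  .writeTSV(manifest, file.path(outDir, "manifest.tsv"))

  invisible(list(study = study, partition = partition, filters = filters,
                 enrichment = enrichment, sas = sasTables,
                 overlap = overlap, concordance = concordance,
                 manifest = manifest))
}
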