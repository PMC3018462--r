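test_that("configuration invariants are enforced", {
  expect_s4_class(syntheticConfig(), "SyntheticConfig")
  expect_error(syntheticConfig(natFraction = 1.2), "fractions")
  expect_error(syntheticConfig(overlapWeights = c(head_to_head = 0.5,
                                                  tail_to_tail = 0.6,
                                                  fully_overlapping = 0.2)),
               "sum to 1")
  expect_error(syntheticConfig(detectP = 50, detectM = 100), "detectM")
  expect_error(syntheticConfig(lengthRange = c(10L, 20L), probeLength = 25L),
               "probeLength")
})

test_that("antisense planting follows natFraction at the extremes", {
  g0 <- generateTranscriptome(syntheticConfig(nGenes = 15, natFraction = 0,
                                              seed = 2))
  ori0 <- S4Vectors::mcols(transcriptLoci(g0$transcriptome))$orientation
  expect_false(any(ori0 == "antisense"))
  d0 <- designPlatforms(g0$transcriptome, syntheticConfig(nGenes = 15,
                                                          natFraction = 0,
                                                          seed = 2), g0$truth)
  expect_length(d0$truth@plantedSASGenes, 0L)

  cfg1 <- syntheticConfig(nGenes = 10, natFraction = 1, sharedFraction = 1,
                          seed = 2)
  g1 <- generateTranscriptome(cfg1)
  ori1 <- S4Vectors::mcols(transcriptLoci(g1$transcriptome))$orientation
  expect_identical(sum(ori1 == "antisense"), 10L)
  d1 <- designPlatforms(g1$transcriptome, cfg1, g1$truth)
  expect_length(d1$truth@plantedSASGenes, 10L)
})

test_that("antisense count at natFraction 0.2 falls in its binomial band", {
  g <- generateTranscriptome(syntheticConfig(nGenes = 1000, seed = 7))
  nAs <- sum(S4Vectors::mcols(transcriptLoci(g$transcriptome))$orientation ==
               "antisense")
  band <- qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(nAs, band[1])
  expect_lte(nAs, band[2])
})

test_that("probes are verbatim substrings of their source transcript", {
  cfg <- syntheticConfig(nGenes = 25, seed = 13)
  g <- generateTranscriptome(cfg)
  d <- designPlatforms(g$transcriptome, cfg, g$truth)
  seqs <- as.character(transcriptSeqs(g$transcriptome))
  for (pd in list(d$generic, d$dsa)) {
    anno <- as.data.frame(probesetAnnotation(pd))
    pr <- as.character(probes(pd))
    psOf <- sub("_p[0-9]+$", "", names(pr))
    txOf <- anno$transcript_id[match(psOf, anno$probeset_id)]
    ok <- mapply(function(p, tx) grepl(p, seqs[[tx]], fixed = TRUE), pr, txOf)
    expect_true(all(ok))
  }
})

test_that("planted overlap geometry matches the assigned category", {
  cfg <- syntheticConfig(nGenes = 150, natFraction = 0.6, seed = 17)
  g <- generateTranscriptome(cfg)
  loci <- transcriptLoci(g$transcriptome)
  truthCat <- g$truth@categoryByGene
  expect_gt(length(truthCat), 0L)
  for (gid in names(truthCat)) {
    got <- classifyOverlapCategory(loci[paste0(gid, "_S")],
                                   loci[paste0(gid, "_AS")])
    expect_identical(got, unname(truthCat[gid]))
  }
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- syntheticConfig(nGenes = 20, seed = 31)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(as.character(transcriptSeqs(a$transcriptome)),
                   as.character(transcriptSeqs(b$transcriptome)))
  expect_identical(intensities(a$invitroDsa), intensities(b$invitroDsa))
  expect_identical(flagCalls(a$clinical), flagCalls(b$clinical))
  expect_identical(commonProbesets(a$truth), commonProbesets(b$truth))
})

test_that("noiseless planting yields exact fold changes and clean flags", {
  cfg <- syntheticConfig(nGenes = 40, deFraction = 0.3, noiseSdLog2 = 0,
                         flagFlipRate = 0, effectLog2 = 1,
                         baselineLog2Sd = 0, seed = 5)
  st <- simulateStudy(cfg)
  e <- log2(intensities(st$invitroDsa))
  cd <- as.data.frame(SummarizedExperiment::colData(st$invitroDsa))
  lfc <- rowMeans(e[, cd$condition == "parental_5FU"]) -
    rowMeans(e[, cd$condition == "parental_untreated"])
  anno <- as.data.frame(probesetAnnotation(st$dsa))
  planted <- st$truth@plantedDE$sensitive
  onPlat <- planted[planted$transcript_id %in% anno$transcript_id, ]
  expect_gt(nrow(onPlat), 0L)
  ps <- anno$probeset_id[match(onPlat$transcript_id, anno$transcript_id)]
  expect_equal(unname(lfc[ps]), onPlat$sign, tolerance = 1e-12)
  expect_true(all(lfc[setdiff(rownames(e), anno$probeset_id[
    anno$transcript_id %in% planted$transcript_id])] == 0))
})

test_that("flags track the linear-intensity thresholds", {
  cfg <- syntheticConfig(nGenes = 15, baselineLog2Mean = 2,
                         baselineLog2Sd = 0, noiseSdLog2 = 0,
                         deFraction = 0, flagFlipRate = 0, seed = 3)
  st <- simulateStudy(cfg)
  expect_true(all(flagCalls(st$invitroDsa) == "A"))

  cfgP <- syntheticConfig(nGenes = 15, baselineLog2Mean = 12,
                          baselineLog2Sd = 0, noiseSdLog2 = 0,
                          deFraction = 0, flagFlipRate = 0, seed = 3)
  stP <- simulateStudy(cfgP)
  expect_true(all(flagCalls(stP$invitroDsa) == "P"))
})

test_that("expression simulation rejects unknown design labels", {
  cfg <- syntheticConfig(nGenes = 10, seed = 4)
  st <- simulateStudy(cfg)
  bad <- makeInvitroDesign(2)
  bad$condition[1] <- "mystery_condition"
  expect_error(simulateExpression(st$dsa, bad, st$truth, cfg),
               "unknown condition")
  badc <- makeClinicalDesign(8)
  badc$response[1] <- "XX"
  expect_error(simulateExpression(st$dsa, badc, st$truth, cfg),
               "unknown response")
})
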