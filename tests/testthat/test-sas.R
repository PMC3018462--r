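test_that("orientation-specific deduplication collapses to gene ids", {
  anno <- data.frame(
    probeset_id = paste0("p", 1:10),
    gene_id = c("G1", "G1", "G2", "G3", "G4", "G5", "G6", "G6", NA, NA),
    orientation = c(rep("sense", 8), "sense", "antisense"))
  g <- dedupeByGene(anno, "sense")
  expect_setequal(as.character(g), paste0("G", 1:6))
  expect_identical(attr(g, "n_unannotated"), 1L)
  expect_length(dedupeByGene(anno[9:10, ], "antisense"), 0L)
})

test_that("SAS pairs are the genes present in both orientations", {
  t1 <- findSASPairs(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(pairedGenes(t1), c("B", "C"))
  expect_identical(nrow(sasPairs(t1)), 2L)
  t2 <- findSASPairs(c("A", "B"), c("C", "D"))
  expect_identical(nrow(sasPairs(t2)), 0L)
  # cardinality bound holds on random sets
  set.seed(3)
  for (i in 1:20) {
    s <- sample(letters, sample(5:20, 1))
    a <- sample(letters, sample(5:20, 1))
    tt <- findSASPairs(s, a)
    expect_lte(nrow(sasPairs(tt)), min(length(unique(s)), length(unique(a))))
  }
})

test_that("overlap categories follow the 5'/3' end-containment rule", {
  gr <- function(s, e, st) GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(s, e), st)
  # sense [101,500]+ vs antisense [401,800]-: overlap holds both 3' ends
  expect_identical(classifyOverlapCategory(gr(101, 500, "+"),
                                           gr(401, 800, "-")),
                   "tail_to_tail")
  # sense [101,500]+ vs antisense [51,200]-: overlap holds both 5' ends
  expect_identical(classifyOverlapCategory(gr(101, 500, "+"),
                                           gr(51, 200, "-")),
                   "head_to_head")
  # containment wins regardless of ends
  expect_identical(classifyOverlapCategory(gr(101, 500, "+"),
                                           gr(51, 600, "-")),
                   "fully_overlapping")
  expect_identical(classifyOverlapCategory(gr(101, 500, "+"),
                                           gr(601, 700, "-")),
                   "non_overlapping")
  expect_error(classifyOverlapCategory(gr(1, 10, "+"), gr(5, 15, "+")),
               "opposite strands")
  expect_error(classifyOverlapCategory(
    gr(1, 10, "+"),
    GenomicRanges::GRanges("chr2", IRanges::IRanges(5, 15), "-")),
    "same chromosome")
})

test_that("the category classifier is exhaustive and mutually exclusive", {
  set.seed(21)
  cats <- c("head_to_head", "tail_to_tail", "fully_overlapping",
            "non_overlapping")
  for (i in 1:200) {
    s1 <- sample(1000, 1); e1 <- s1 + sample(50:400, 1)
    s2 <- sample(1000, 1); e2 <- s2 + sample(50:400, 1)
    st <- sample(c("+", "-"), 1)
    sense <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1), st)
    anti <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, e2),
                                   setdiff(c("+", "-"), st))
    got <- classifyOverlapCategory(sense, anti)
    expect_true(got %in% cats)
    # independent re-derivation from interval arithmetic
    if (e1 < s2 || e2 < s1) {
      expect_identical(got, "non_overlapping")
    } else if ((s2 >= s1 && e2 <= e1) || (s1 >= s2 && e1 <= e2)) {
      expect_identical(got, "fully_overlapping")
    } else {
      f1 <- if (st == "+") s1 else e1
      f2 <- if (st == "+") e2 else s2   # antisense has the opposite strand
      ovS <- max(s1, s2); ovE <- min(e1, e2)
      expect_identical(got,
                       if (f1 >= ovS && f1 <= ovE && f2 >= ovS && f2 <= ovE)
                         "head_to_head" else "tail_to_tail")
    }
  }
})

test_that("concordance labels use a strict two-fold boundary", {
  expect_identical(labelConcordance(100, 100), "concordant")
  expect_identical(labelConcordance(100, 400), "discordant")
  expect_identical(labelConcordance(100, 200), "concordant")  # exactly 2-fold
  expect_identical(labelConcordance(100, 201), "discordant")
  expect_error(labelConcordance(0, 100), "positive")
})

test_that("orientation percentages are half-up rounded and sum to 100", {
  anno <- data.frame(probeset_id = sprintf("p%05d", 1:23089),
                     orientation = rep(c("sense", "antisense", "unassigned"),
                                       c(11320, 9754, 2015)))
  ob <- orientationBreakdown(anno)
  expect_identical(ob$count, c(11320L, 9754L, 2015L))
  expect_identical(ob$percent, c(49.03, 42.25, 8.73))
  expect_lte(abs(sum(ob$percent) - 100), 0.02)
})

test_that("cross-experiment overlaps count shared genes per class", {
  full <- list(sense = letters[1:10], antisense = letters[3:12],
               pairs = letters[5:9])
  same <- crossExperimentOverlap(list(a = full, b = full))
  expect_identical(same$overlap,
                   c(10L, 10L, 5L))
  disj <- crossExperimentOverlap(list(
    a = full, b = list(sense = LETTERS[1:4], antisense = LETTERS[5:8],
                       pairs = character())))
  expect_identical(disj$overlap, c(0L, 0L, 0L))
  clin <- list(sense = character(), antisense = character(),
               pairs = sprintf("sas%02d", 1:8))
  vitro <- list(sense = character(), antisense = character(),
                pairs = c(sprintf("sas%02d", 1:7), sprintf("x%02d", 1:38)))
  ov <- crossExperimentOverlap(list(clinical = clin, invitro = vitro))
  expect_identical(ov$overlap[ov$class == "pairs"], 7L)
})

test_that("planted SAS pairs and their categories are recovered when all
           transcripts are detected", {
  cfg <- syntheticConfig(nGenes = 80, natFraction = 0.4,
                         baselineLog2Mean = 12, baselineLog2Sd = 0.5,
                         flagFlipRate = 0, seed = 43)
  st <- simulateStudy(cfg)
  anno <- probesetAnnotation(st$dsa)
  detected <- Reduce(intersect, lapply(
    unique(SummarizedExperiment::colData(st$invitroDsa)$condition),
    function(cc) detectInVitro(st$invitroDsa, cc)))
  expect_setequal(detected, as.character(anno$probeset_id))
  pt <- findSASPairs(dedupeByGene(anno, "sense", detected),
                     dedupeByGene(anno, "antisense", detected),
                     annotation = anno,
                     meanIntensity = rowMeans(intensities(st$invitroDsa)),
                     loci = transcriptLoci(st$transcriptome))
  expect_setequal(pairedGenes(pt), st$truth@plantedSASGenes)
  pr <- as.data.frame(sasPairs(pt))
  expect_identical(unname(st$truth@categoryByGene[pr$gene_id]), pr$category)
  expect_true(all(pr$concordance %in% c("concordant", "discordant")))
})
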