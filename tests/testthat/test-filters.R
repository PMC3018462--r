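test_that("in-vitro detection requires Present/Marginal in every replicate", {
  e <- matrix(200, 3, 4, dimnames = list(paste0("ps", 1:3), NULL))
  f <- rbind(c("P", "P", "M", "P"),
             c("P", "A", "P", "P"),
             c("M", "M", "M", "M"))
  x <- makeFlagged(e, f, conditions = c("a", "a", "a", "b"))
  expect_setequal(detectInVitro(x, "a"), c("ps1", "ps3"))
  # degenerate single-replicate condition: one Marginal call suffices
  expect_setequal(detectInVitro(x, "b"), c("ps1", "ps2", "ps3"))
  expect_error(detectInVitro(x, "nope"), "unknown condition")
})

test_that("clinical detection uses a strict majority of all samples", {
  e <- matrix(200, 3, 28, dimnames = list(paste0("ps", 1:3), NULL))
  f <- rbind(c(rep("P", 15), rep("A", 13)),   # 15/28 passes
             c(rep("P", 14), rep("A", 14)),   # 14/28 is exactly 50%: fails
             rep("A", 28))
  x <- makeFlagged(e, f, response = rep(c("CR", "PR", "SD", "PD"), 7))
  expect_identical(detectClinical(x), "ps1")
  fAll <- matrix("A", 3, 28)
  xAll <- makeFlagged(e, fAll, response = rep(c("CR", "PR", "SD", "PD"), 7))
  expect_length(detectClinical(xAll), 0L)
})

test_that("the in-vitro cascade applies fold and t-test rules exactly", {
  la <- c(0, 0.1, -0.1); lb <- c(1, 1.1, 0.9)
  e <- rbind(ps_de   = 2^c(la, lb),
             ps_flat = rep(150, 6),
             ps_bound = c(99, 100, 101, 129, 130, 131),
             ps_degen = c(100, 100, 100, 200, 200, 200))
  colnames(e) <- paste0("s", 1:6)
  f <- matrix("P", nrow(e), 6, dimnames = dimnames(e))
  x <- makeFlagged(e, f, conditions = rep(c("ctl", "trt"), each = 3))
  res <- deFilter(x, "ctl", "trt")
  st <- as.data.frame(deStats(res))
  rownames(st) <- st$probeset_id

  # closed-form pooled t on 4 df for the worked fixture
  expect_equal(st["ps_de", "p_value"], 2 * pt(-sqrt(150), 4),
               tolerance = 1e-12)
  expect_equal(st["ps_de", "fold_change"], mean(2^lb) / mean(2^la),
               tolerance = 1e-12)
  expect_true("ps_de" %in% deProbesets(res))

  # identical replicate vectors: fold exactly 1, never differentially expressed
  expect_equal(st["ps_flat", "fold_change"], 1)
  expect_false("ps_flat" %in% deProbesets(res))

  # fold threshold is inclusive at 1.3
  expect_equal(st["ps_bound", "fold_change"], 1.3)
  expect_true("ps_bound" %in% deProbesets(res))

  # zero variance with unequal means: degenerate, treated as p = 0
  expect_true(st["ps_degen", "degenerate"])
  expect_identical(st["ps_degen", "p_value"], 0)
  expect_true("ps_degen" %in% deProbesets(res))
})

test_that("pooled t matches stats::t.test on random fixtures", {
  set.seed(99)
  for (i in 1:20) {
    a <- 2^rnorm(3, 7, 0.5); b <- 2^rnorm(3, 7.5, 0.5)
    e <- rbind(ps1 = c(a, b))
    colnames(e) <- paste0("s", 1:6)
    f <- matrix("P", 1, 6, dimnames = dimnames(e))
    x <- makeFlagged(e, f, conditions = rep(c("u", "t"), each = 3))
    res <- as.data.frame(deStats(deFilter(x, "u", "t")))
    oracle <- t.test(log2(b), log2(a), var.equal = TRUE)$p.value
    expect_equal(res$p_value, oracle, tolerance = 1e-12)
  }
})

test_that("the clinical cascade passes on a 1.5-fold one-vs-rest contrast", {
  resp <- rep(c("CR", "PR", "SD", "PD"), each = 7)
  mk <- function(means) {
    e <- rbind(ps1 = means[match(resp, c("CR", "PR", "SD", "PD"))])
    colnames(e) <- paste0("s", 1:28)
    f <- matrix("P", 1, 28, dimnames = dimnames(e))
    makeFlagged(e, f, response = resp)
  }
  expect_length(deProbesets(deFilterClinical(mk(c(10, 10, 10, 10)))), 0L)
  # one group exactly 1.5x the rest passes (inclusive threshold)
  r <- deFilterClinical(mk(c(15, 10, 10, 10)))
  expect_identical(deProbesets(r), "ps1")
  expect_equal(as.data.frame(deStats(r))$fold_change, 1.5)
  # group means (10, 10, 10, 16): fold 1.6 in the PD group
  r2 <- deFilterClinical(mk(c(10, 10, 10, 16)))
  st2 <- as.data.frame(deStats(r2))
  expect_equal(st2$fold_change, 1.6)
  expect_identical(st2$group, "PD")
})

test_that("differential expression is nested in detection", {
  st <- simulateStudy(syntheticConfig(nGenes = 50, seed = 61))
  for (cmp in list(c("parental_untreated", "parental_5FU"),
                   c("resistant_untreated", "resistant_5FU"))) {
    r <- deFilter(st$invitroDsa, cmp[1], cmp[2])
    expect_true(all(deProbesets(r) %in% detectedProbesets(r)))
  }
  rc <- deFilterClinical(st$clinical)
  expect_true(all(deProbesets(rc) %in% detectedProbesets(rc)))
})

test_that("tightening thresholds never enlarges the DE set", {
  st <- simulateStudy(syntheticConfig(nGenes = 60, deFraction = 0.3,
                                      seed = 67))
  base <- deProbesets(deFilter(st$invitroDsa, "parental_untreated",
                               "parental_5FU", 1.3, 0.05))
  higherFold <- deProbesets(deFilter(st$invitroDsa, "parental_untreated",
                                     "parental_5FU", 1.6, 0.05))
  lowerP <- deProbesets(deFilter(st$invitroDsa, "parental_untreated",
                                 "parental_5FU", 1.3, 0.01))
  expect_true(all(higherFold %in% base))
  expect_true(all(lowerP %in% base))
})

test_that("detection is invariant to sample order within a condition", {
  st <- simulateStudy(syntheticConfig(nGenes = 30, seed = 71))
  x <- st$invitroDsa
  perm <- sample(ncol(x))
  e <- intensities(x)[, perm]
  f <- flagCalls(x)[, perm]
  cd <- as.data.frame(SummarizedExperiment::colData(x))[perm, ]
  xp <- makeFlagged(e, f, conditions = cd$condition)
  for (cond in unique(cd$condition))
    expect_setequal(detectInVitro(x, cond), detectInVitro(xp, cond))
})
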