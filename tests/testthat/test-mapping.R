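test_that("the exact-match index finds words on both strands", {
  idx <- indexSequences(c(T1 = "ACGTTTGA"))
  hit <- queryIndex(idx, "GTTT")   # present forward; revcomp AAAC is not
  expect_identical(hit$target_id, "T1")
  expect_identical(hit$strand, "forward")

  pal <- queryIndex(idx, "ACGT")   # its own reverse complement
  expect_setequal(pal$strand, c("forward", "reverse"))

  set.seed(42)
  targets <- setNames(replicate(5, randomSeq(300)), paste0("T", 1:5))
  idx2 <- indexSequences(targets)
  probe <- randomSeq(25)
  while (any(naiveCounts(probe, targets) > 0)) probe <- randomSeq(25)
  expect_identical(nrow(queryIndex(idx2, probe)), 0L)

  expect_error(indexSequences(Biostrings::DNAStringSet()), "empty")
})

test_that("probeset matching counts probes per single sequence", {
  set.seed(7)
  targets <- setNames(replicate(7, randomSeq(400)), paste0("T", 1:7))
  idx <- indexSequences(targets)

  # all 11 probes in T1
  all11 <- substring(targets[["T1"]], seq(1, 301, 30), seq(25, 325, 30))[1:11]
  m <- matchProbeset(all11, idx, "ps_all")
  expect_identical(m$best_target, "T1")
  expect_identical(m$n_probes_matched_to_best, 11L)

  # 6 probes in T2, 5 scattered over T3..T7: the rule demands one sequence
  six <- substring(targets[["T2"]], seq(1, 151, 30), seq(25, 175, 30))
  scattered <- vapply(paste0("T", 3:7), function(t)
    substring(targets[[t]], 50, 74), character(1))
  m2 <- matchProbeset(c(six, scattered), idx, "ps_six")
  expect_identical(m2$best_target, "T2")
  expect_identical(m2$n_probes_matched_to_best, 6L)

  # 5 in T1 and 5 in T2, never pooling
  five1 <- substring(targets[["T1"]], seq(1, 121, 30), seq(25, 145, 30))
  five2 <- substring(targets[["T2"]], seq(200, 320, 30), seq(224, 344, 30))
  m3 <- matchProbeset(c(five1, five2), idx, "ps_split")
  expect_identical(m3$n_probes_matched_to_best, 5L)
  expect_identical(m3$best_target, "T1")  # tie broken to the smaller id
})

test_that("reverse-complement probes count toward the match", {
  set.seed(11)
  tg <- setNames(randomSeq(300), "T1")
  idx <- indexSequences(tg)
  fwd <- substring(tg, seq(1, 91, 30), seq(25, 115, 30))
  rev <- rcChar(substring(tg, seq(130, 220, 30), seq(154, 244, 30)))
  m <- matchProbeset(c(fwd, rev), idx, "ps")
  expect_identical(m$n_probes_matched_to_best, 8L)
})

test_that("identical content is all common; disjoint content all unique", {
  set.seed(19)
  seqs <- setNames(replicate(4, randomSeq(300)), paste0("TX", 1:4))
  mk <- function(name, prefix, full) {
    pss <- lapply(names(full), function(tx) {
      list(tx = tx, probes = substring(full[[tx]], seq(1, 271, 27),
                                       seq(25, 295, 27))[1:11])
    })
    names(pss) <- paste0(prefix, names(full))
    makePlatform(name, full, pss)
  }
  a <- mk("generic", "A_", seqs)
  b <- mk("dsa", "B_", seqs)
  pa <- classifyCommonUnique(a, b)
  expect_length(uniqueProbesets(pa), 0L)
  expect_setequal(commonProbesets(pa),
                  c(paste0("A_TX", 1:4), paste0("B_TX", 1:4)))

  other <- setNames(replicate(4, randomSeq(300)), paste0("TY", 1:4))
  b2 <- mk("dsa", "B_", other)
  pb <- classifyCommonUnique(a, b2)
  expect_length(commonProbesets(pb), 0L)
  expect_identical(sort(unname(partitionSummary(pb)[, "Unique"])),
                   c(4L, 4L))
})

test_that("partition law holds and truth is recovered on synthetic platforms", {
  cfg <- syntheticConfig(nGenes = 60, seed = 23)
  st <- simulateStudy(cfg)
  pa <- classifyCommonUnique(st$generic, st$dsa)
  sm <- partitionSummary(pa)
  expect_identical(unname(sm[, "Common"] + sm[, "Unique"]),
                   unname(sm[, "Total"]))
  expect_setequal(commonProbesets(pa), commonProbesets(st$truth))
})

test_that("breaking a sixth probe flips common to unique; adding never does", {
  set.seed(29)
  full <- setNames(randomSeq(400), "TX1")
  sixMatch <- substring(full, seq(1, 151, 30), seq(25, 175, 30))
  nonMatch <- replicate(5, randomSeq(25))
  while (any(naiveCounts(nonMatch, full) > 0)) nonMatch <- replicate(5, randomSeq(25))
  a <- makePlatform("generic", full,
                    list(A_TX1 = list(tx = "TX1",
                                      probes = substring(full, 1, 380))))
  mkB <- function(pr) makePlatform("dsa", c(BX1 = randomSeq(400)),
                                   list(B_PS1 = list(tx = "BX1", probes = pr)))
  atSix <- classifyCommonUnique(a, mkB(c(sixMatch, nonMatch)))
  expect_identical(unname(partitionTable(atSix)$class[
    partitionTable(atSix)$probeset_id == "B_PS1"]), "common")

  broken <- c(sixMatch[1:5], randomSeq(25), nonMatch)
  atFive <- classifyCommonUnique(a, mkB(broken))
  expect_identical(unname(partitionTable(atFive)$class[
    partitionTable(atFive)$probeset_id == "B_PS1"]), "unique")

  extra <- c(sixMatch, substring(full, 200, 224), nonMatch)
  atSeven <- classifyCommonUnique(a, mkB(extra))
  expect_identical(unname(partitionTable(atSeven)$class[
    partitionTable(atSeven)$probeset_id == "B_PS1"]), "common")
})

test_that("match counts are invariant to reverse-complementing the targets", {
  set.seed(37)
  targets <- setNames(replicate(6, randomSeq(350)), paste0("T", 1:6))
  probesets <- lapply(1:4, function(i) {
    tx <- paste0("T", i)
    substring(targets[[tx]], seq(10, 160, 30), seq(34, 184, 30))
  })
  idxF <- indexSequences(targets)
  idxR <- indexSequences(setNames(rcChar(targets), names(targets)))
  for (i in seq_along(probesets)) {
    mF <- matchProbeset(probesets[[i]], idxF, "ps")
    mR <- matchProbeset(probesets[[i]], idxR, "ps")
    expect_identical(mF$n_probes_matched_to_best, mR$n_probes_matched_to_best)
    expect_identical(mF$best_target, mR$best_target)
    expect_false(identical(mF$strand_of_best, mR$strand_of_best))
  }
})

test_that("probesets without a sequence record are reported, not dropped silently", {
  set.seed(41)
  full <- setNames(randomSeq(300), "TX1")
  a <- makePlatform("generic", full,
                    list(A1 = list(tx = "TX1",
                                   probes = substring(full, seq(1, 271, 27),
                                                      seq(25, 295, 27))[1:11]),
                         A2 = list(tx = "TX_MISSING",
                                   probes = replicate(11, randomSeq(25)))))
  b <- makePlatform("dsa", setNames(randomSeq(300), "BX1"),
                    list(B1 = list(tx = "BX1",
                                   probes = replicate(11, randomSeq(25)))))
  expect_warning(pa <- classifyCommonUnique(a, b), "excluded")
  expect_identical(pa@excluded, "A2")
  expect_false("A2" %in% partitionTable(pa)$probeset_id)
})
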