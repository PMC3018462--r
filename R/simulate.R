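#' @include AllClasses.R
NULL

#' Construct a synthetic study configuration
#'
#' Returns a validated [SyntheticConfig]. The defaults emulate the study
#' design the package targets: two partially overlapping array platforms
#' (a generic sense-only design with per-gene probeset redundancy and a
#' disease-specific design carrying sense, antisense and a small
#' unannotated stratum), probesets of 11 probes x 25 nt, triplicate
#' in-vitro conditions (parental/resistant, untreated/5-FU) and a
#' 28-sample clinical cohort with four response groups. Noise and effect
#' magnitudes are stand-ins chosen for a realistic array experiment — the
#' design being emulated reports none — and are documented in the package
#' vignette.
#'
#' @param nGenes number of genes.
#' @param natFraction probability a gene carries an antisense partner.
#' @param overlapWeights named probabilities over `head_to_head`,
#'   `tail_to_tail`, `fully_overlapping`.
#' @param lengthRange sense transcript length range (nt).
#' @param probeLength probe length (nt).
#' @param probesPerProbeset probes per probeset.
#' @param sharedFraction fraction of genes on both platforms.
#' @param redundancyGeneric mean probesets per gene on the generic array.
#' @param unassignedFraction target share of disease-specific probesets
#'   without orientation annotation.
#' @param deFraction fraction of transcripts with a planted effect per
#'   comparison.
#' @param effectLog2 planted log2 fold-change magnitude.
#' @param noiseSdLog2 replicate noise SD (log2 scale).
#' @param baselineLog2Mean,baselineLog2Sd baseline log2 intensity
#'   distribution.
#' @param detectP,detectM linear-intensity thresholds for Present and
#'   Marginal calls.
#' @param flagFlipRate probability a flag call is corrupted.
#' @param nReps replicates per in-vitro condition.
#' @param nClinical clinical sample count.
#' @param seed master seed.
#' @return a [SyntheticConfig].
#' @export
#' @examples
#' cfg <- syntheticConfig(nGenes = 50, seed = 7)
#' cfg
syntheticConfig <- function(nGenes = 300L,
                            natFraction = 0.2,
                            overlapWeights = c(head_to_head = 0.3,
                                               tail_to_tail = 0.5,
                                               fully_overlapping = 0.2),
                            lengthRange = c(400L, 2000L),
                            probeLength = 25L,
                            probesPerProbeset = 11L,
                            sharedFraction = 0.55,
                            redundancyGeneric = 1.8,
                            unassignedFraction = 0.09,
                            deFraction = 0.05,
                            effectLog2 = 1,
                            noiseSdLog2 = 0.25,
                            baselineLog2Mean = 8,
                            baselineLog2Sd = 1.2,
                            detectP = 100,
                            detectM = 50,
                            flagFlipRate = 0.01,
                            nReps = 3L,
                            nClinical = 28L,
                            seed = 1L) {
  new("SyntheticConfig",
      nGenes = .assertCount(nGenes, "nGenes"),
      natFraction = natFraction,
      overlapWeights = overlapWeights[c("head_to_head", "tail_to_tail",
                                        "fully_overlapping")],
      lengthRange = as.integer(lengthRange),
      probeLength = .assertCount(probeLength, "probeLength"),
      probesPerProbeset = .assertCount(probesPerProbeset, "probesPerProbeset"),
      sharedFraction = sharedFraction,
      redundancyGeneric = redundancyGeneric,
      unassignedFraction = unassignedFraction,
      deFraction = deFraction,
      effectLog2 = effectLog2,
      noiseSdLog2 = noiseSdLog2,
      baselineLog2Mean = baselineLog2Mean,
      baselineLog2Sd = baselineLog2Sd,
      detectP = detectP,
      detectM = detectM,
      flagFlipRate = flagFlipRate,
      nReps = .assertCount(nReps, "nReps"),
      nClinical = .assertCount(nClinical, "nClinical"),
      seed = .assertCount(seed, "seed", min = 0L))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nGenes, "genes, NAT fraction",
      object@natFraction, ", shared fraction", object@sharedFraction, "\n")
  cat("  probes:", object@probesPerProbeset, "x", object@probeLength,
      "nt; effect", object@effectLog2, "log2; noise SD",
      object@noiseSdLog2, "; seed", object@seed, "\n")
})

# random DNA of given width as a character string
.randomDNA <- function(w) {
  paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
}

#' Generate a toy transcriptome with planted sense-antisense structure
#'
#' Every gene yields one sense transcript at its own genomic locus; a
#' `natFraction` share of genes additionally yields a natural antisense
#' transcript on the opposite strand of the same locus whose overlap
#' geometry follows its assigned cis-NAT category: `head_to_head` overlaps
#' both transcripts' 5' ends, `tail_to_tail` both 3' ends, and
#' `fully_overlapping` places the antisense entirely inside the sense.
#' A stratum of orientation-unassigned transcripts (without gene ids)
#' emulates unannotated array content. Transcript sequences are extracted
#' from a shared random genomic sequence per locus, so opposite-strand
#' transcripts are reverse complements over their overlap, exactly as for
#' a real cis-NAT. Planted differential-expression effects for the
#' sensitive, resistant and clinical comparisons are drawn here and
#' recorded in the returned [GroundTruth].
#'
#' @param config a [SyntheticConfig].
#' @return a list with elements `transcriptome` (a [Transcriptome]) and
#'   `truth` (a [GroundTruth]; `commonProbesets` and `plantedSASGenes` are
#'   filled in by [designPlatforms()]).
#' @seealso [designPlatforms()], [simulateExpression()], [simulateStudy()]
#' @export
#' @examples
#' gt <- generateTranscriptome(syntheticConfig(nGenes = 20, seed = 3))
#' gt$transcriptome
generateTranscriptome <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (config@probeLength > min(config@lengthRange))
    stop("transcript length range shorter than the probe length")
  set.seed(.stageSeed(config@seed, 1L))

  n  <- config@nGenes
  lr <- config@lengthRange
  pl <- config@probeLength
  geneIds <- sprintf("G%05d", seq_len(n))

  lenS    <- sample(seq(lr[1], lr[2]), n, replace = TRUE)
  strandS <- sample(c("+", "-"), n, replace = TRUE)
  isNat   <- runif(n) < config@natFraction
  categ   <- sample(names(config@overlapWeights), n, replace = TRUE,
                    prob = config@overlapWeights)

  # genomic layout: disjoint windows per gene, rotating over chromosomes,
  # with margins wide enough for any antisense extension
  nChrom <- 6L
  chrom  <- paste0("chr", (seq_len(n) - 1L) %% nChrom + 1L)
  margin <- lr[2] + 100L
  winW   <- lenS + 2L * margin
  cursor <- integer(nChrom)
  s <- integer(n)
  for (i in seq_len(n)) {
    ci <- (i - 1L) %% nChrom + 1L
    s[i] <- cursor[ci] + margin + 1L
    cursor[ci] <- cursor[ci] + winW[i]
  }
  e <- s + lenS - 1L

  # antisense geometry per category
  aStart <- aEnd <- rep(NA_integer_, n)
  for (i in which(isNat)) {
    if (categ[i] == "fully_overlapping") {
      lenA <- max(100L, as.integer(round(runif(1, 0.3, 0.8) * (lenS[i] - 20L))))
      d1 <- sample.int(lenS[i] - lenA - 1L, 1L)
      aStart[i] <- s[i] + d1
      aEnd[i]   <- aStart[i] + lenA - 1L
    } else {
      lenA <- sample(seq(lr[1], lr[2]), 1L)
      m   <- min(lenS[i], lenA)
      ovl <- min(max(pl, as.integer(round(runif(1, 0.15, 0.7) * m))), m - 10L)
      headward <- (categ[i] == "head_to_head") == (strandS[i] == "+")
      if (headward) {           # antisense extends 5'-ward of the + coordinate
        aEnd[i]   <- s[i] + ovl - 1L
        aStart[i] <- aEnd[i] - lenA + 1L
      } else {                  # antisense extends 3'-ward
        aStart[i] <- e[i] - ovl + 1L
        aEnd[i]   <- aStart[i] + lenA - 1L
      }
    }
  }

  # orientation-unassigned stratum, sized to its expected share of the
  # disease-specific content
  eSpecific <- n * ((1 - config@sharedFraction) + config@natFraction)
  uf <- config@unassignedFraction
  nUn <- if (uf > 0 && eSpecific > 0)
    as.integer(round(uf / (1 - uf) * eSpecific)) else 0L
  lenU <- if (nUn) sample(seq(lr[1], lr[2]), nUn, replace = TRUE) else integer()
  sU <- eU <- integer(nUn)
  chromU <- if (nUn) paste0("chr", (seq_len(nUn) - 1L) %% nChrom + 1L) else character()
  for (j in seq_len(nUn)) {
    ci <- (j - 1L) %% nChrom + 1L
    sU[j] <- cursor[ci] + margin + 1L
    cursor[ci] <- cursor[ci] + lenU[j] + 2L * margin
  }
  eU <- sU + lenU - 1L
  strandU <- if (nUn) sample(c("+", "-"), nUn, replace = TRUE) else character()

  # sequences: one random genomic region per locus; transcripts extracted
  # by strand so overlapping transcripts are reverse complements
  txId <- c(paste0(geneIds, "_S"),
            if (any(isNat)) paste0(geneIds[isNat], "_AS") else character(),
            if (nUn) sprintf("U%05d_X", seq_len(nUn)) else character())
  txGene <- c(geneIds, geneIds[isNat], rep(NA_character_, nUn))
  txOri <- c(rep("sense", n), rep("antisense", sum(isNat)),
             rep("unassigned", nUn))
  txChrom <- c(chrom, chrom[isNat], chromU)
  txStart <- c(s, aStart[isNat], sU)
  txEnd   <- c(e, aEnd[isNat], eU)
  txStrand <- c(strandS, chartr("+-", "-+", strandS[isNat]), strandU)

  # one random genomic region per locus (gene regions first, then the
  # unassigned loci); transcript sequences are cut from these regions
  regSeq <- character(n + nUn)
  r0Region <- integer(n + nUn)
  for (i in seq_len(n)) {
    r0 <- if (isNat[i]) min(s[i], aStart[i]) else s[i]
    r1 <- if (isNat[i]) max(e[i], aEnd[i]) else e[i]
    r0Region[i] <- r0
    regSeq[i] <- .randomDNA(r1 - r0 + 1L)
  }
  for (j in seq_len(nUn)) {
    r0Region[n + j] <- sU[j]
    regSeq[n + j] <- .randomDNA(lenU[j])
  }

  regOf <- c(seq_len(n), which(isNat), if (nUn) n + seq_len(nUn) else integer())
  r0All <- r0Region[regOf]
  plus <- substring(regSeq[regOf], txStart - r0All + 1L, txEnd - r0All + 1L)
  seqs <- DNAStringSet(plus)
  minus <- txStrand == "-"
  if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
  names(seqs) <- txId

  loci <- GRanges(txChrom, IRanges(txStart, txEnd), strand = txStrand)
  names(loci) <- txId
  S4Vectors::mcols(loci)$gene_id <- txGene
  S4Vectors::mcols(loci)$orientation <- txOri

  # planted differential expression per comparison
  nd <- as.integer(round(config@deFraction * length(txId)))
  plantOne <- function(clinical = FALSE) {
    ids <- if (nd) sample(txId, nd) else character()
    df <- data.frame(transcript_id = ids,
                     sign = if (nd) sample(c(-1, 1), nd, replace = TRUE) else numeric(),
                     stringsAsFactors = FALSE)
    if (clinical)
      df$group <- if (nd) sample(c("CR", "PR", "SD", "PD"), nd, replace = TRUE)
                  else character()
    df
  }
  truth <- new("GroundTruth",
               commonProbesets = character(),
               plantedDE = list(sensitive = plantOne(),
                                resistant = plantOne(),
                                clinical = plantOne(clinical = TRUE)),
               plantedSASGenes = character(),
               categoryByGene = stats::setNames(categ[isNat], geneIds[isNat]))

  list(transcriptome = new("Transcriptome", loci = loci, seqs = seqs),
       truth = truth)
}

# sample probe start offsets (transcript coordinates) for one probeset
.probeStarts <- function(txLen, nProbes, probeLen) {
  nPos <- txLen - probeLen + 1L
  sort(sample.int(nPos, nProbes, replace = nPos < nProbes))
}

#' Design the generic and disease-specific platforms
#'
#' Splits the gene catalogue into shared, generic-only and
#' disease-specific-only content, then builds both platform designs. The
#' generic platform carries sense transcripts only, with on average
#' `redundancyGeneric` probesets per gene; the disease-specific platform
#' carries one probeset per sense transcript, per antisense transcript of
#' its genes, and per orientation-unassigned transcript. Probes are
#' verbatim substrings of their source transcript. The returned
#' [GroundTruth] gains `plantedSASGenes` and `commonProbesets`; the latter
#' is derived purely from locus geometry (a probe "matches" a transcript on
#' the other platform when its genomic footprint lies inside that
#' transcript's locus) pushed through the same bidirectional
#' six-probes-per-sequence cascade that [classifyCommonUnique()] applies to
#' sequences — so sequence-level recovery of the truth is a genuine
#' cross-check, not a tautology.
#'
#' @param transcriptome a [Transcriptome] from [generateTranscriptome()].
#' @param config the [SyntheticConfig] used to generate it.
#' @param truth the matching [GroundTruth].
#' @return list with elements `generic` and `dsa` (both [PlatformDesign])
#'   and the augmented `truth`.
#' @export
designPlatforms <- function(transcriptome, config, truth) {
  stopifnot(is(transcriptome, "Transcriptome"), is(config, "SyntheticConfig"),
            is(truth, "GroundTruth"))
  loci <- transcriptome@loci
  seqs <- transcriptome@seqs
  if (length(loci) == 0L) stop("transcriptome is empty")
  mc <- S4Vectors::mcols(loci)
  set.seed(.stageSeed(config@seed, 2L))

  geneIds <- mc$gene_id[mc$orientation == "sense"]
  n <- length(geneIds)
  perm <- sample(geneIds)
  nShared <- as.integer(round(config@sharedFraction * n))
  shared <- perm[seq_len(nShared)]
  rest <- setdiff(perm, shared)
  genericOnly <- rest[seq_along(rest) %% 2L == 1L]
  dsaOnly <- setdiff(rest, genericOnly)
  genericGenes <- sort(c(shared, genericOnly))
  dsaGenes <- sort(c(shared, dsaOnly))

  pp <- config@probesPerProbeset
  pl <- config@probeLength
  txLen <- stats::setNames(width(loci), names(loci))

  buildProbes <- function(psId, txOfPs) {
    starts <- unlist(lapply(txOfPs, function(t)
      .probeStarts(txLen[[t]], pp, pl)), use.names = FALSE)
    txRep <- rep(txOfPs, each = pp)
    psRep <- rep(psId, each = pp)
    pr <- subseq(seqs[txRep], start = starts, width = pl)
    names(pr) <- paste0(psRep, "_p", formatC(seq_len(pp), width = 2, flag = "0"))
    list(probes = pr,
         map = data.frame(probeset_id = psRep, transcript_id = txRep,
                          start = starts, stringsAsFactors = FALSE))
  }

  # generic platform: redundant sense probesets
  kRed <- 1L + rpois(length(genericGenes), config@redundancyGeneric - 1)
  genTx <- rep(paste0(genericGenes, "_S"), kRed)
  genPs <- unlist(lapply(seq_along(genericGenes), function(i)
    sprintf("GEN_%s_S_%02d", genericGenes[i], seq_len(kRed[i]))),
    use.names = FALSE)
  genBuilt <- buildProbes(genPs, genTx)
  genAnno <- DataFrame(probeset_id = genPs, transcript_id = genTx,
                       gene_id = rep(genericGenes, kRed),
                       orientation = "sense")

  # disease-specific platform: sense + antisense + unassigned
  natGenes <- names(truth@categoryByGene)
  dsaNat <- intersect(dsaGenes, natGenes)
  dsaTx <- c(paste0(dsaGenes, "_S"),
             if (length(dsaNat)) paste0(sort(dsaNat), "_AS") else character(),
             sort(names(loci)[mc$orientation == "unassigned"]))
  dsaPs <- paste0("DSA_", dsaTx)
  dsaBuilt <- buildProbes(dsaPs, dsaTx)
  dsaAnno <- DataFrame(
    probeset_id = dsaPs, transcript_id = dsaTx,
    gene_id = mc$gene_id[match(dsaTx, names(loci))],
    orientation = mc$orientation[match(dsaTx, names(loci))])

  generic <- new("PlatformDesign", platformName = "generic",
                 probes = genBuilt$probes, annotation = genAnno,
                 fullLength = seqs[unique(genTx)])
  dsa <- new("PlatformDesign", platformName = "dsa",
             probes = dsaBuilt$probes, annotation = dsaAnno,
             fullLength = seqs[dsaTx])

  # geometric ground-truth match counts (coordinates, not sequences)
  geomHits <- function(map, queryAnno, targetAnno) {
    tStart <- start(loci); tEnd <- end(loci); tStr <- as.character(strand(loci))
    i <- match(map$transcript_id, names(loci))
    gs <- ifelse(tStr[i] == "+", tStart[i] + map$start - 1L,
                 tEnd[i] - map$start - pl + 2L)
    ge <- gs + pl - 1L
    gene <- queryAnno$gene_id[match(map$probeset_id, queryAnno$probeset_id)]
    tGene <- targetAnno$gene_id
    out <- list()
    for (ps in unique(map$probeset_id)) {
      rows <- map$probeset_id == ps
      g <- gene[match(ps, map$probeset_id)]
      if (is.na(g)) next
      targets <- unique(targetAnno$transcript_id[!is.na(tGene) & tGene == g])
      for (tt in targets) {
        j <- match(tt, names(loci))
        cnt <- sum(gs[rows] >= tStart[j] & ge[rows] <= tEnd[j])
        if (cnt > 0L)
          out[[length(out) + 1L]] <- data.frame(
            probeset_id = ps, target_id = tt, n = cnt,
            stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(probeset_id = character(), target_id = character(),
                    n = integer(), stringsAsFactors = FALSE)
  }
  dsaGeom <- geomHits(dsaBuilt$map, dsaAnno, genAnno)
  genGeom <- geomHits(genBuilt$map, genAnno, dsaAnno)
  tp <- .twoPassCommon(dsaGeom, genGeom,
                       as.data.frame(dsaAnno), as.data.frame(genAnno),
                       minProbes = 6L)

  truth@commonProbesets <- sort(c(tp$aCommon, tp$bCommon))
  truth@plantedSASGenes <- sort(dsaNat)
  validObject(truth)
  list(generic = generic, dsa = dsa, truth = truth)
}

#' Experiment design tables
#'
#' `makeInvitroDesign()` builds the replicated two-cell-line, two-treatment
#' design (parental/resistant, untreated/5-FU); `makeClinicalDesign()`
#' builds a clinical cohort with response groups CR/PR/SD/PD assigned in
#' rotation.
#'
#' @param nReps replicates per condition.
#' @return a data.frame with a `sample_id` column and either
#'   `condition`/`replicate` or `response`.
#' @export
#' @examples
#' makeInvitroDesign(3)
makeInvitroDesign <- function(nReps = 3L) {
  nReps <- .assertCount(nReps, "nReps")
  conds <- c("parental_untreated", "parental_5FU",
             "resistant_untreated", "resistant_5FU")
  data.frame(
    sample_id = paste0(rep(conds, each = nReps), "_r", seq_len(nReps)),
    condition = rep(conds, each = nReps),
    replicate = rep(seq_len(nReps), times = length(conds)),
    stringsAsFactors = FALSE)
}

#' @rdname makeInvitroDesign
#' @param n number of clinical samples.
#' @export
makeClinicalDesign <- function(n = 28L) {
  n <- .assertCount(n, "n")
  resp <- rep(c("CR", "PR", "SD", "PD"), length.out = n)
  data.frame(sample_id = sprintf("patient_%02d", seq_len(n)),
             response = resp, stringsAsFactors = FALSE)
}

#' Simulate expression and flag calls for a platform
#'
#' Log2 intensities are a per-transcript baseline plus the planted effect
#' (for planted transcripts, in the affected condition or response group)
#' plus Gaussian replicate noise. Flag calls are derived by thresholding
#' the linear intensity — Present above `detectP`, Marginal between the
#' thresholds, Absent below — and then corrupted at `flagFlipRate` (a
#' corrupted call becomes one of the other two classes at random). The
#' result is deterministic for a fixed configuration seed.
#'
#' @param platform a [PlatformDesign].
#' @param design a design table from [makeInvitroDesign()] or
#'   [makeClinicalDesign()].
#' @param truth the [GroundTruth] carrying the planted effects.
#' @param config the [SyntheticConfig].
#' @return a [FlaggedExperiment].
#' @export
simulateExpression <- function(platform, design, truth, config) {
  stopifnot(is(platform, "PlatformDesign"), is.data.frame(design),
            is(truth, "GroundTruth"), is(config, "SyntheticConfig"))
  invitro <- all(c("condition", "replicate") %in% colnames(design))
  clinical <- "response" %in% colnames(design)
  if (!invitro && !clinical)
    stop("design must provide condition/replicate or response columns")
  conds <- c("parental_untreated", "parental_5FU",
             "resistant_untreated", "resistant_5FU")
  if (invitro && !all(design$condition %in% conds))
    stop("unknown condition labels: ",
         paste(setdiff(design$condition, conds), collapse = ", "))
  if (clinical && !all(design$response %in% c("CR", "PR", "SD", "PD")))
    stop("unknown response labels: ",
         paste(setdiff(design$response, c("CR", "PR", "SD", "PD")),
               collapse = ", "))

  anno <- platform@annotation
  tx <- anno$transcript_id
  ns <- nrow(design)
  set.seed(.stageSeed(config@seed, 3L,
                      .labelSalt(c(platform@platformName,
                                   if (invitro) "invitro" else "clinical", ns))))

  txIds <- unique(tx)
  base <- stats::setNames(
    rnorm(length(txIds), config@baselineLog2Mean, config@baselineLog2Sd), txIds)
  M <- matrix(base[tx], nrow = nrow(anno), ncol = ns)

  addEffect <- function(M, planted, cols) {
    if (!nrow(planted) || !any(cols)) return(M)
    i <- match(tx, planted$transcript_id)
    hit <- !is.na(i)
    M[hit, cols] <- M[hit, cols] +
      planted$sign[i[hit]] * config@effectLog2
    M
  }
  if (invitro) {
    M <- addEffect(M, truth@plantedDE$sensitive,
                   design$condition == "parental_5FU")
    M <- addEffect(M, truth@plantedDE$resistant,
                   design$condition == "resistant_5FU")
  } else {
    pl <- truth@plantedDE$clinical
    for (g in unique(pl$group))
      M <- addEffect(M, pl[pl$group == g, , drop = FALSE],
                     design$response == g)
  }
  if (config@noiseSdLog2 > 0)
    M <- M + matrix(rnorm(length(M), 0, config@noiseSdLog2), nrow(M))

  E <- 2^M
  FL <- matrix("A", nrow(E), ncol(E))
  FL[E > config@detectM] <- "M"
  FL[E > config@detectP] <- "P"
  if (config@flagFlipRate > 0) {
    flip <- runif(length(FL)) < config@flagFlipRate
    if (any(flip)) {
      pick <- runif(sum(flip)) < 0.5
      others <- vapply(FL[flip], function(f)
        setdiff(c("P", "M", "A"), f)[1:2], character(2))
      FL[flip] <- ifelse(pick, others[1L, ], others[2L, ])
    }
  }
  dimnames(E) <- dimnames(FL) <- list(anno$probeset_id, design$sample_id)
  FlaggedExperiment(E, FL, design)
}

#' Simulate a complete synthetic study
#'
#' Runs the three generation stages — transcriptome, platform designs,
#' expression — from a single configuration, each on its own RNG stream
#' derived from the master seed. Produces the in-vitro experiment on both
#' platforms and the clinical cohort on the disease-specific platform.
#'
#' @param config a [SyntheticConfig].
#' @return a list with elements `config`, `transcriptome`, `truth`,
#'   `generic`, `dsa`, `invitroDsa`, `invitroGeneric`, `clinical`.
#' @export
#' @examples
#' study <- simulateStudy(syntheticConfig(nGenes = 30, seed = 11))
#' study$dsa
simulateStudy <- function(config = syntheticConfig()) {
  gen <- generateTranscriptome(config)
  des <- designPlatforms(gen$transcriptome, config, gen$truth)
  invitro <- makeInvitroDesign(config@nReps)
  clin <- makeClinicalDesign(config@nClinical)
  list(config = config,
       transcriptome = gen$transcriptome,
       truth = des$truth,
       generic = des$generic,
       dsa = des$dsa,
       invitroDsa = simulateExpression(des$dsa, invitro, des$truth, config),
       invitroGeneric = simulateExpression(des$generic, invitro, des$truth,
                                           config),
       clinical = simulateExpression(des$dsa, clin, des$truth, config))
}

#' Build a synthetic pathway database
#'
#' Random gene sets over a gene universe, optionally with one planted
#' pathway drawn preferentially from a supplied gene list so that
#' enrichment has signal to find. Used by [runFullPipeline()] to exercise
#' pathway over-representation on synthetic data.
#'
#' @param universe character, gene ids to draw from.
#' @param nPathways number of random pathways.
#' @param sizeRange pathway size range.
#' @param plantedGenes genes to concentrate in the planted pathway.
#' @param plantedName name of the planted pathway.
#' @return named list of gene-id character vectors.
#' @export
makeSyntheticPathways <- function(universe, nPathways = 25L,
                                  sizeRange = c(10L, 60L),
                                  plantedGenes = character(),
                                  plantedName = "planted_response_pathway") {
  stopifnot(length(universe) > 0L)
  sizes <- sample(seq(sizeRange[1], min(sizeRange[2], length(universe))),
                  nPathways, replace = TRUE)
  db <- lapply(sizes, function(k) sample(universe, k))
  names(db) <- sprintf("random_pathway_%02d", seq_len(nPathways))
  if (length(plantedGenes)) {
    core <- sample(plantedGenes, min(25L, length(plantedGenes)))
    pad <- sample(setdiff(universe, core),
                  max(0L, min(5L, length(universe) - length(core))))
    db[[plantedName]] <- c(core, pad)
  }
  db
}
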