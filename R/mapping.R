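#' @include AllClasses.R
NULL

#' Build an exact-match index over full-length sequences
#'
#' Prepares a sequence set for exact probe lookup on both strands. Because
#' the common/unique rule demands 100% identity over the entire probe,
#' exact substring matching is sufficient and fully reproducible — no
#' alignment heuristics, no e-values. Reverse-complement hits are indexed
#' so antisense probesets can match sense sequences.
#'
#' @param sequences a named [Biostrings::DNAStringSet] (or named character
#'   vector) of full-length sequences.
#' @return a [ProbeIndex].
#' @export
#' @examples
#' idx <- indexSequences(c(T1 = "ACGTACGTACGT"))
#' queryIndex(idx, "GTAC")
indexSequences <- function(sequences) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (length(sequences) == 0L) stop("cannot index an empty sequence set")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  new("ProbeIndex", subject = sequences,
      rcSubject = reverseComplement(sequences))
}

setMethod("show", "ProbeIndex", function(object) {
  cat("ProbeIndex over", length(object@subject),
      "sequences (both strands),",
      sum(width(object@subject)), "nt total\n")
})

# which query words occur in which subject sequences; queries of mixed
# width are grouped because the dictionary matcher needs constant width
.whichHits <- function(queries, subject) {
  hits <- vector("list", length(subject))
  for (i in seq_along(hits)) hits[[i]] <- integer()
  byW <- split(seq_along(queries), width(queries))
  for (idx in byW) {
    q <- queries[idx]
    names(q) <- NULL
    pd <- PDict(q)
    got <- vwhichPDict(pd, subject)
    for (i in seq_along(subject))
      hits[[i]] <- c(hits[[i]], idx[got[[i]]])
  }
  hits
}

#' Query an exact-match index
#'
#' Exact lookup of words against the indexed sequences; a word hits the
#' forward strand when it occurs in the sequence as given and the reverse
#' strand when it occurs in the reverse complement.
#'
#' @param index a [ProbeIndex].
#' @param kmers character vector or `DNAStringSet` of query words.
#' @return a data.frame with columns `query`, `target_id`, `strand`
#'   (one row per hit; zero rows when nothing matches).
#' @export
queryIndex <- function(index, kmers) {
  stopifnot(is(index, "ProbeIndex"))
  if (is.character(kmers)) kmers <- DNAStringSet(kmers)
  if (length(kmers) == 0L)
    return(data.frame(query = character(), target_id = character(),
                      strand = character(), stringsAsFactors = FALSE))
  qn <- if (is.null(names(kmers))) as.character(kmers) else names(kmers)
  fwd <- .whichHits(kmers, index@subject)
  rev <- .whichHits(kmers, index@rcSubject)
  tid <- names(index@subject)
  out <- list()
  for (i in seq_along(tid)) {
    if (length(fwd[[i]]))
      out[[length(out) + 1L]] <- data.frame(
        query = qn[fwd[[i]]], target_id = tid[i], strand = "forward",
        stringsAsFactors = FALSE)
    if (length(rev[[i]]))
      out[[length(out) + 1L]] <- data.frame(
        query = qn[rev[[i]]], target_id = tid[i], strand = "reverse",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(query = character(), target_id = character(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$query, res$target_id, res$strand), , drop = FALSE]
}

# per-(probeset, target) distinct-probe match counts for a set of probes
# grouped by probesetOf; returns probeset_id, target_id, n, n_fwd, n_rev
.probeHitTable <- function(probeSeqs, probesetOf, index) {
  tid <- names(index@subject)
  fwd <- .whichHits(probeSeqs, index@subject)
  rev <- .whichHits(probeSeqs, index@rcSubject)
  out <- list()
  for (i in seq_along(tid)) {
    hitIdx <- union(fwd[[i]], rev[[i]])
    if (!length(hitIdx)) next
    ps <- probesetOf[hitIdx]
    isF <- hitIdx %in% fwd[[i]]
    agg <- tapply(seq_along(hitIdx), ps, function(j)
      c(n = length(j), n_fwd = sum(isF[j])))
    df <- do.call(rbind, agg)
    out[[length(out) + 1L]] <- data.frame(
      probeset_id = rownames(df), target_id = tid[i],
      n = as.integer(df[, "n"]), n_fwd = as.integer(df[, "n_fwd"]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(probeset_id = character(), target_id = character(),
                      n = integer(), n_fwd = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Match one probeset against indexed sequences
#'
#' Counts, per candidate target sequence, how many of the probeset's
#' probes occur exactly (over their entire length, on either strand) in
#' that single sequence — probes matching different sequences never pool.
#' The best target is the sequence with the maximal count; ties break to
#' the lexicographically smallest target id.
#'
#' @param probeSeqs character vector or `DNAStringSet` of the probeset's
#'   probes.
#' @param index a [ProbeIndex] over the other platform's full-length
#'   sequences.
#' @param probesetId id recorded in the result.
#' @return a one-row data.frame: `probeset_id`, `best_target`,
#'   `n_probes_matched_to_best`, `strand_of_best` (`forward`/`reverse`,
#'   the strand carrying the majority of the matched probes), with
#'   `best_target = NA` when no probe matches anywhere.
#' @export
#' @examples
#' idx <- indexSequences(c(T1 = "ACGTTTGACCAGT"))
#' matchProbeset(c("ACGTT", "GACCA", "TTTTT"), idx)
matchProbeset <- function(probeSeqs, index, probesetId = "probeset") {
  stopifnot(is(index, "ProbeIndex"))
  if (is.character(probeSeqs)) probeSeqs <- DNAStringSet(probeSeqs)
  if (length(probeSeqs) == 0L) stop("a probeset needs at least one probe")
  hits <- .probeHitTable(probeSeqs, rep(probesetId, length(probeSeqs)), index)
  if (!nrow(hits))
    return(data.frame(probeset_id = probesetId, best_target = NA_character_,
                      n_probes_matched_to_best = 0L,
                      strand_of_best = NA_character_,
                      stringsAsFactors = FALSE))
  best <- hits[order(-hits$n, hits$target_id), ][1L, ]
  data.frame(probeset_id = probesetId,
             best_target = best$target_id,
             n_probes_matched_to_best = best$n,
             strand_of_best = if (best$n_fwd * 2L >= best$n) "forward"
                              else "reverse",
             stringsAsFactors = FALSE)
}

# the bidirectional two-pass common/unique cascade, shared between the
# sequence-level classifier and the generator's geometric ground truth.
# hitsB: disease-specific probesets vs platform-A sequences;
# hitsA: platform-A probesets vs disease-specific sequences.
.twoPassCommon <- function(hitsB, hitsA, annoB, annoA, minProbes = 6L) {
  q1 <- hitsB[hitsB$n >= minProbes, , drop = FALSE]
  bCommon <- unique(q1$probeset_id)
  aCommon <- annoA$probeset_id[annoA$transcript_id %in% unique(q1$target_id)]
  bRemSeqs <- unique(annoB$transcript_id[!annoB$probeset_id %in% bCommon])
  q2 <- hitsA[hitsA$n >= minProbes & hitsA$target_id %in% bRemSeqs, ,
              drop = FALSE]
  aCommon <- union(aCommon, unique(q2$probeset_id))
  bCommon <- union(bCommon,
                   annoB$probeset_id[annoB$transcript_id %in%
                                       unique(q2$target_id)])
  list(aCommon = sort(aCommon), bCommon = sort(bCommon))
}

#' Partition two platforms into common and unique content
#'
#' Applies the six-probes-per-probeset rule bidirectionally. Pass 1: each
#' probeset of `platformB` (the disease-specific side) is matched against
#' the full-length sequences of `platformA`; where at least `minProbes`
#' probes occur exactly in one sequence, that probeset and the probesets
#' represented by the hit sequence are marked common. Pass 2: `platformA`
#' probesets are matched against the full-length sequences representing the
#' `platformB` probesets not yet common, with the same rule marking both
#' sides common. Everything else is unique. Probesets with fewer than
#' `minProbes` probes can never be common; probesets whose source
#' transcript has no sequence record are excluded and reported rather than
#' silently dropped.
#'
#' @param platformA,platformB two [PlatformDesign] objects; `platformB`
#'   plays the disease-specific role (queried first).
#' @param minProbes minimum probes matching one sequence (default 6).
#' @return a [ContentPartition].
#' @seealso [commonProbesets()], [uniqueProbesets()], [partitionSummary()]
#' @export
classifyCommonUnique <- function(platformA, platformB, minProbes = 6L) {
  stopifnot(is(platformA, "PlatformDesign"), is(platformB, "PlatformDesign"))
  minProbes <- .assertCount(minProbes, "minProbes")
  annoA <- as.data.frame(platformA@annotation)
  annoB <- as.data.frame(platformB@annotation)

  excl <- c(annoA$probeset_id[!annoA$transcript_id %in%
                                names(platformA@fullLength)],
            annoB$probeset_id[!annoB$transcript_id %in%
                                names(platformB@fullLength)])
  annoA <- annoA[!annoA$probeset_id %in% excl, , drop = FALSE]
  annoB <- annoB[!annoB$probeset_id %in% excl, , drop = FALSE]

  psOfA <- sub("_p[0-9]+$", "", names(platformA@probes))
  psOfB <- sub("_p[0-9]+$", "", names(platformB@probes))
  keepA <- psOfA %in% annoA$probeset_id
  keepB <- psOfB %in% annoB$probeset_id

  idxA <- indexSequences(platformA@fullLength)
  idxB <- indexSequences(platformB@fullLength)
  hitsB <- .probeHitTable(platformB@probes[keepB], psOfB[keepB], idxA)
  hitsA <- .probeHitTable(platformA@probes[keepA], psOfA[keepA], idxB)

  tp <- .twoPassCommon(hitsB, hitsA, annoB, annoA, minProbes)

  bestOf <- function(anno, hits) {
    out <- data.frame(probeset_id = anno$probeset_id,
                      best_target = NA_character_, n_matched = 0L,
                      strand = NA_character_, stringsAsFactors = FALSE)
    if (nrow(hits)) {
      hits <- hits[order(-hits$n, hits$target_id), , drop = FALSE]
      first <- hits[!duplicated(hits$probeset_id), , drop = FALSE]
      i <- match(out$probeset_id, first$probeset_id)
      hit <- !is.na(i)
      out$best_target[hit] <- first$target_id[i[hit]]
      out$n_matched[hit] <- first$n[i[hit]]
      out$strand[hit] <- ifelse(first$n_fwd[i[hit]] * 2L >= first$n[i[hit]],
                                "forward", "reverse")
    }
    out
  }
  tabA <- bestOf(annoA, hitsA)
  tabA$platform <- platformA@platformName
  tabA$class <- ifelse(tabA$probeset_id %in% tp$aCommon, "common", "unique")
  tabB <- bestOf(annoB, hitsB)
  tabB$platform <- platformB@platformName
  tabB$class <- ifelse(tabB$probeset_id %in% tp$bCommon, "common", "unique")

  tab <- rbind(tabA, tabB)[, c("probeset_id", "platform", "class",
                               "best_target", "n_matched", "strand")]
  if (length(excl))
    warning(length(excl),
            " probeset(s) had no full-length sequence record and were excluded")
  new("ContentPartition", table = DataFrame(tab),
      platforms = c(platformA@platformName, platformB@platformName),
      minProbes = minProbes, excluded = unique(excl))
}
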