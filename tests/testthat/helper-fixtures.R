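# Shared fixtures and independent oracles, all built in code.

# reverse complement of a plain character string (independent of Biostrings)
rcChar <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# naive O(n*m) substring-scan oracle: distinct probes of a probeset found
# in each target on either strand
naiveCounts <- function(probeSeqs, targets) {
  vapply(targets, function(tg) {
    sum(vapply(probeSeqs, function(p)
      grepl(p, tg, fixed = TRUE) || grepl(rcChar(p), tg, fixed = TRUE),
      logical(1)))
  }, integer(1))
}

naiveBest <- function(probeSeqs, targets) {
  cnt <- naiveCounts(probeSeqs, targets)
  if (all(cnt == 0L))
    return(list(target = NA_character_, n = 0L))
  best <- names(cnt)[cnt == max(cnt)]
  list(target = sort(best)[1L], n = max(cnt))
}

# build a PlatformDesign from plain character data;
# probesets: named list of list(tx = <transcript id>, probes = character())
makePlatform <- function(name, fullLength, probesets,
                         gene = NULL, orientation = NULL) {
  ps <- names(probesets)
  if (is.null(gene)) gene <- setNames(rep(NA_character_, length(ps)), ps)
  if (is.null(orientation))
    orientation <- setNames(rep("sense", length(ps)), ps)
  allProbes <- unlist(lapply(ps, function(id) {
    pr <- probesets[[id]]$probes
    setNames(pr, paste0(id, "_p", formatC(seq_along(pr), width = 2,
                                          flag = "0")))
  }))
  new("PlatformDesign",
      platformName = name,
      probes = Biostrings::DNAStringSet(allProbes),
      annotation = S4Vectors::DataFrame(
        probeset_id = ps,
        transcript_id = vapply(probesets, `[[`, character(1), "tx"),
        gene_id = unname(gene[ps]),
        orientation = unname(orientation[ps])),
      fullLength = Biostrings::DNAStringSet(fullLength))
}

# build a FlaggedExperiment from matrices and a condition or response vector
makeFlagged <- function(exprs, flags, conditions = NULL, response = NULL) {
  if (is.null(colnames(exprs)))
    colnames(exprs) <- paste0("s", seq_len(ncol(exprs)))
  if (is.null(rownames(exprs)))
    rownames(exprs) <- paste0("ps", seq_len(nrow(exprs)))
  dimnames(flags) <- dimnames(exprs)
  if (!is.null(conditions)) {
    design <- data.frame(sample_id = colnames(exprs),
                         condition = conditions,
                         replicate = stats::ave(seq_along(conditions),
                                                conditions, FUN = seq_along))
  } else {
    design <- data.frame(sample_id = colnames(exprs), response = response)
  }
  FlaggedExperiment(exprs, flags, design)
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate every size-n draw from N elements, K of which are "pathway"
enumHyperTail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
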