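#' @include AllClasses.R
NULL

#' Construct a FlaggedExperiment
#'
#' Binds a linear-scale expression matrix, a parallel Present/Marginal/
#' Absent flag matrix, and a design table into a [FlaggedExperiment]. The
#' design is either replicated in-vitro conditions (columns `condition`,
#' `replicate`) or a clinical cohort (column `response` with values
#' CR/PR/SD/PD); its `sample_id` column must match the matrix columns.
#'
#' @param exprs numeric matrix, probesets x samples, positive intensities.
#' @param flags character matrix of `"P"`, `"M"`, `"A"`, same dimnames.
#' @param design data.frame with `sample_id` plus design columns.
#' @return a [FlaggedExperiment].
#' @export
#' @examples
#' e <- matrix(2^rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("ps", 1:3), paste0("s", 1:4)))
#' f <- matrix("P", 3, 4, dimnames = dimnames(e))
#' d <- data.frame(sample_id = colnames(e),
#'                 condition = rep(c("a", "b"), each = 2),
#'                 replicate = rep(1:2, 2))
#' FlaggedExperiment(e, f, d)
FlaggedExperiment <- function(exprs, flags, design) {
  stopifnot(is.matrix(exprs), is.matrix(flags),
            identical(dim(exprs), dim(flags)), is.data.frame(design))
  if (!identical(dimnames(exprs), dimnames(flags)))
    stop("expression and flag matrices must share identical dimnames")
  if (!"sample_id" %in% colnames(design))
    stop("design must have a sample_id column")
  if (!identical(as.character(design$sample_id), colnames(exprs)))
    stop("design sample ids must match the matrix columns, in order")
  cd <- S4Vectors::DataFrame(design[setdiff(colnames(design), "sample_id")],
                             row.names = design$sample_id)
  se <- SummarizedExperiment(assays = list(exprs = exprs, flags = flags),
                             colData = cd)
  new("FlaggedExperiment", se)
}

.flagsPM <- function(x) flagCalls(x) %in% c("P", "M")

#' Detection filtering of replicated in-vitro conditions
#'
#' A probeset counts as detected in a condition when its flag call is
#' Present or Marginal in every replicate of that condition.
#'
#' @param x a [FlaggedExperiment] with an in-vitro design.
#' @param condition condition label to filter.
#' @return character vector of detected probeset ids.
#' @seealso [detectClinical()], [deFilter()]
#' @export
detectInVitro <- function(x, condition) {
  stopifnot(is(x, "FlaggedExperiment"))
  cd <- SummarizedExperiment::colData(x)
  if (!"condition" %in% colnames(cd))
    stop("experiment has no in-vitro condition design")
  if (!condition %in% cd$condition)
    stop("unknown condition: ", condition)
  f <- flagCalls(x)[, cd$condition == condition, drop = FALSE]
  rownames(f)[rowSums(f == "P" | f == "M") == ncol(f)]
}

#' Detection filtering of a clinical cohort
#'
#' A probeset counts as detected when it is called Present or Marginal in
#' strictly more than half of all samples: 15 of 28 samples pass, 14 of 28
#' do not.
#'
#' @param x a [FlaggedExperiment].
#' @param majorityFraction the strict majority threshold (default 0.5).
#' @return character vector of detected probeset ids.
#' @export
detectClinical <- function(x, majorityFraction = 0.5) {
  stopifnot(is(x, "FlaggedExperiment"))
  .assertFraction(majorityFraction, "majorityFraction")
  pm <- .flagsPM(x)
  dim(pm) <- dim(flagCalls(x))
  rownames(flagCalls(x))[rowMeans(pm) > majorityFraction]
}

# vectorised pooled-variance two-sample t-test on log2 intensities.
# returns p values with the cascade's degenerate-variance conventions:
# both groups constant and equal -> NA; constant but unequal -> 0.
.pooledT <- function(lx, ly) {
  n1 <- ncol(lx); n2 <- ncol(ly)
  m1 <- rowMeans(lx); m2 <- rowMeans(ly)
  v1 <- apply(lx, 1L, stats::var); v2 <- apply(ly, 1L, stats::var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * pt(-abs(tstat), df)
  zeroVar <- sp2 <= 0
  p[zeroVar & m1 == m2] <- NA_real_
  p[zeroVar & m1 != m2] <- 0
  degenerate <- zeroVar & m1 != m2
  list(p = p, t = tstat, degenerate = degenerate)
}

#' Differential-expression filter cascade (in-vitro)
#'
#' Applies the full cascade between two replicated conditions: probesets
#' must first be detected (Present/Marginal in all replicates) in both
#' conditions; fold change is computed on linear-scale replicate means as
#' `max(meanB/meanA, meanA/meanB)` with the direction recorded; the
#' two-sample pooled-variance Student t-test runs on log2 intensities. A
#' probeset is differentially expressed when its fold change reaches
#' `foldThreshold` (inclusive) and its p value is below `pThreshold`
#' (strict). No multiple-testing correction is applied — the cascade
#' mirrors the raw-p filtering convention of the comparison it implements.
#' Zero variance in both groups with equal means yields fold 1 (never
#' passes); zero variance with unequal means is flagged degenerate and
#' treated as p = 0.
#'
#' @param x a [FlaggedExperiment] with an in-vitro design.
#' @param conditionA,conditionB the condition labels to compare (fold and
#'   direction are B relative to A).
#' @param foldThreshold minimum fold change, inclusive (default 1.3).
#' @param pThreshold t-test significance level, strict (default 0.05).
#' @param comparison label stored in the result.
#' @return a [FilterCascadeResult].
#' @export
deFilter <- function(x, conditionA, conditionB,
                     foldThreshold = 1.3, pThreshold = 0.05,
                     comparison = paste(conditionB, "vs", conditionA)) {
  stopifnot(is(x, "FlaggedExperiment"))
  if (foldThreshold < 1) stop("foldThreshold must be >= 1")
  if (pThreshold <= 0 || pThreshold >= 1) stop("pThreshold must be in (0, 1)")
  cd <- SummarizedExperiment::colData(x)
  detected <- intersect(detectInVitro(x, conditionA),
                        detectInVitro(x, conditionB))
  colsA <- cd$condition == conditionA
  colsB <- cd$condition == conditionB
  if (sum(colsA) < 2L || sum(colsB) < 2L)
    stop("the t-test needs at least two replicates per condition")
  if (!length(detected)) {
    return(new("FilterCascadeResult", comparison = comparison,
               detected = character(),
               stats = DataFrame(probeset_id = character(),
                                 fold_change = numeric(),
                                 direction = character(),
                                 p_value = numeric(),
                                 degenerate = logical(), passed = logical()),
               de = character(),
               params = list(foldThreshold = foldThreshold,
                             pThreshold = pThreshold,
                             conditionA = conditionA,
                             conditionB = conditionB)))
  }
  e <- intensities(x)[detected, , drop = FALSE]
  ea <- e[, colsA, drop = FALSE]
  eb <- e[, colsB, drop = FALSE]
  ma <- rowMeans(ea); mb <- rowMeans(eb)
  fold <- pmax(mb / ma, ma / mb)
  tt <- .pooledT(log2(ea), log2(eb))
  pass <- !is.na(tt$p) & fold >= foldThreshold & tt$p < pThreshold
  stats <- DataFrame(
    probeset_id = detected,
    fold_change = fold,
    direction = ifelse(mb >= ma, "up", "down"),
    p_value = tt$p,
    degenerate = tt$degenerate,
    passed = pass)
  new("FilterCascadeResult",
      comparison = comparison,
      detected = detected,
      stats = stats,
      de = detected[pass],
      params = list(foldThreshold = foldThreshold, pThreshold = pThreshold,
                    conditionA = conditionA, conditionB = conditionB))
}

#' Differential-expression filter cascade (clinical)
#'
#' Clinical variant of the cascade: probesets must be detected in strictly
#' more than half of all samples ([detectClinical()]); each response group
#' is then contrasted against the mean of all other samples on the linear
#' scale, and a probeset passes when its fold change reaches
#' `foldThreshold` (inclusive) in at least one response group.
#'
#' @param x a [FlaggedExperiment] with a clinical design.
#' @param foldThreshold minimum one-vs-rest fold change (default 1.5).
#' @param comparison label stored in the result.
#' @return a [FilterCascadeResult]; `p_value` is `NA` (the clinical
#'   cascade applies no statistical test), `direction` refers to the
#'   best-fold group recorded in `group`.
#' @export
deFilterClinical <- function(x, foldThreshold = 1.5,
                             comparison = "clinical") {
  stopifnot(is(x, "FlaggedExperiment"))
  if (foldThreshold < 1) stop("foldThreshold must be >= 1")
  cd <- SummarizedExperiment::colData(x)
  if (!"response" %in% colnames(cd))
    stop("experiment has no clinical response design")
  groups <- c("CR", "PR", "SD", "PD")
  present <- groups[groups %in% cd$response]
  if (length(present) < 2L)
    stop("need at least two response groups")
  if (length(present) < length(groups))
    warning("response group(s) with no samples skipped: ",
            paste(setdiff(groups, present), collapse = ", "))
  detected <- detectClinical(x)
  if (!length(detected)) {
    return(new("FilterCascadeResult", comparison = comparison,
               detected = character(),
               stats = DataFrame(probeset_id = character(),
                                 fold_change = numeric(),
                                 direction = character(),
                                 group = character(),
                                 p_value = numeric(), passed = logical()),
               de = character(),
               params = list(foldThreshold = foldThreshold)))
  }
  e <- intensities(x)[detected, , drop = FALSE]
  foldMat <- sapply(present, function(g) {
    inG <- cd$response == g
    mg <- rowMeans(e[, inG, drop = FALSE])
    mr <- rowMeans(e[, !inG, drop = FALSE])
    pmax(mg / mr, mr / mg)
  })
  if (length(detected) == 1L) foldMat <- matrix(foldMat, nrow = 1L,
                                                dimnames = list(detected, present))
  upMat <- sapply(present, function(g) {
    inG <- cd$response == g
    rowMeans(e[, inG, drop = FALSE]) >= rowMeans(e[, !inG, drop = FALSE])
  })
  if (length(detected) == 1L) upMat <- matrix(upMat, nrow = 1L)
  best <- max.col(foldMat, ties.method = "first")
  fold <- foldMat[cbind(seq_along(detected), best)]
  pass <- fold >= foldThreshold
  stats <- DataFrame(
    probeset_id = detected,
    fold_change = as.numeric(fold),
    direction = ifelse(upMat[cbind(seq_along(detected), best)], "up", "down"),
    group = present[best],
    p_value = NA_real_,
    passed = pass)
  new("FilterCascadeResult",
      comparison = comparison,
      detected = detected,
      stats = stats,
      de = detected[pass],
      params = list(foldThreshold = foldThreshold))
}
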