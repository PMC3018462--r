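#' @include AllClasses.R
NULL

#' Sign-preserving log2 transform of signed fold changes
#'
#' Signed fold-change ratios (negative meaning down-regulation, by the
#' usual reporting convention) are mapped to `sign(x) * log2(|x|)`, so
#' +2-fold becomes +1 and -4-fold becomes -2. The log base cancels in a
#' correlation; base 2 is the field's convention. Ratios with magnitude
#' below 1 are accepted with a warning (they land in the (-1, 1) band).
#'
#' @param folds numeric vector of signed fold-change ratios (nonzero).
#' @return numeric vector of signed log2 fold changes, order preserved.
#' @export
#' @examples
#' logTransformFolds(c(2, -4, 1))
logTransformFolds <- function(folds) {
  if (!is.numeric(folds) || any(!is.finite(folds)))
    stop("fold changes must be finite numbers")
  if (any(folds == 0)) stop("fold changes must be nonzero")
  if (any(abs(folds) < 1))
    warning("fold-change magnitude below 1; expected a ratio convention")
  sign(folds) * log2(abs(folds))
}

#' Pearson correlation with its t-based p value
#'
#' The product-moment correlation between paired fold changes (typically
#' array versus qPCR, both log transformed), with `r^2` and the two-sided
#' p value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), not constant.
#' @return list with elements `r`, `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' pearsonWithP(c(1, 2, 3), c(2, 4, 7))
pearsonWithP <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs for a p value")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(r = r, r_squared = r^2, p_value = p, n = n)
}

#' Array-versus-qPCR concordance on paired fold changes
#'
#' Convenience wrapper: log transforms both columns of a paired
#' fold-change table ([logTransformFolds()]) and correlates them
#' ([pearsonWithP()]).
#'
#' @param pairs data.frame with numeric columns `array_fold` and
#'   `qpcr_fold` (signed ratios).
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
concordanceFromFolds <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("array_fold", "qpcr_fold") %in% colnames(pairs)))
  pearsonWithP(logTransformFolds(pairs$array_fold),
               logTransformFolds(pairs$qpcr_fold))
}
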