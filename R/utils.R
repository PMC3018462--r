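# Internal helpers shared across modules.

#' Round half-up at a fixed number of decimals
#'
#' Base R's `round()` rounds half-to-even; summary tables here use the
#' half-up convention consistently, so 42.245 renders as 42.25.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' roundHalfUp(42.245, 2)
roundHalfUp <- function(x, digits = 0L) {
  stopifnot(is.numeric(x), digits >= 0L)
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly .5 in decimal
  # but stored just below it in binary still round up
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# log(sum(exp(lx))) without overflow; lx may contain -Inf
.logSumExp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# per-stage RNG seed derived from the master seed; stays below 2^31
.stageSeed <- function(seed, stage, salt = 0L) {
  s <- (abs(as.integer(seed)) %% 1000003L)
  as.integer((s * 101L + as.integer(stage) * 7919L + as.integer(salt) %% 9973L) %%
               2147483647L)
}

# deterministic integer salt from a character label
.labelSalt <- function(label) {
  as.integer(sum(utf8ToInt(paste(label, collapse = ""))) %% 9973L)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single value in [0, 1]", call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}
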