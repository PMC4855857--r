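# Agreement statistics for method comparison.

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks
#' are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Bland-Altman bias
#'
#' Differences `d = x - y`; returns the mean difference (bias) and the
#' sample (n-1) standard deviation of the differences, the usual
#' "mean +/- SD" convention for method comparison.
#'
#' @param x,y numeric vectors of equal length (n >= 2), e.g. infarct sizes
#'   by two methods.
#' @return list with `bias` and `sd`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 paired measurements")
  d <- x - y
  list(bias = mean(d), sd = stats::sd(d))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors (n >= 3), both with non-zero variance.
#' @return Pearson R.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 paired measurements")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  stats::cor(x, y)
}
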