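#' Power to detect a quantitative trait locus
#'
#' Power of a 1-df additive association test for a SNP explaining a
#' proportion `r2` of the trait variance in `n` unrelated subjects, at
#' two-sided significance level `alpha`. The test statistic is taken as
#' non-central chi-square with 1 df and non-centrality `n * r2 / (1 - r2)`
#' (exact for the variance-explained parameterization); the chi-square
#' approximation to the F(1, n-2) test is below reporting precision at the
#' sample sizes of interest.
#'
#' @param n sample size (>= 4).
#' @param r2 proportion of trait variance explained, in `[0, 1)`.
#' @param alpha significance level in `(0, 1)`.
#' @return Achieved power in `[0, 1]`; equals `alpha` at `r2 = 0`.
#' @export
power_qtl <- function(n, r2, alpha) {
  if (any(n < 4)) stop("n must be >= 4")
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  ncp <- n * r2 / (1 - r2)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Minimal detectable variance explained
#'
#' Smallest `r2` at which [power_qtl()] reaches the target power, found by
#' bisection to an `r2` tolerance of 1e-8. Monotone decreasing in `n` and
#' in `alpha`.
#'
#' @param n sample size.
#' @param alpha significance level.
#' @param power target power in `(alpha, 1)`.
#' @param tol bisection tolerance on `r2`.
#' @return Minimal `r2` in `(0, 1)`.
#' @export
min_detectable_r2 <- function(n, alpha, power, tol = 1e-8) {
  if (power <= alpha || power >= 1)
    stop("target power must lie in (alpha, 1)")
  lo <- 0; hi <- 1 - 1e-12
  if (power_qtl(n, hi, alpha) < power)
    stop("target power unreachable for any r2 in [0, 1)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (power_qtl(n, mid, alpha) >= power) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Required sample size for a quantitative trait locus
#'
#' Smallest integer `n` with [power_qtl()] at least the target power;
#' monotone decreasing in `r2`.
#'
#' @param r2 proportion of trait variance explained, in `(0, 1)`.
#' @param alpha significance level.
#' @param power target power in `(alpha, 1)`.
#' @return Smallest sufficient integer sample size.
#' @export
required_n <- function(r2, alpha, power) {
  if (r2 <= 0) stop("r2 must be positive (power unreachable at r2 = 0)")
  if (power <= alpha || power >= 1)
    stop("target power must lie in (alpha, 1)")
  lo <- 4L
  hi <- 8L
  while (power_qtl(hi, r2, alpha) < power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > .Machine$integer.max / 2) stop("required n exceeds integer range")
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (power_qtl(mid, r2, alpha) >= power) hi <- mid else lo <- mid
  }
  if (power_qtl(lo, r2, alpha) >= power) lo else hi
}
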