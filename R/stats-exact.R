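## Exact tests.
##
## The two-sided Fisher p-value uses the minimum-likelihood
## definition: the sum, over all 2x2 tables with the observed margins,
## of hypergeometric probabilities no larger than that of the observed
## table. This is the convention of fisher.test() and reproduces the
## hand-checkable published table p-values; it is implemented here
## directly (fisher.test serves as an independent cross-check in the
## test suite, never as the implementation).

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Tests association in the 2x2 table
#' \preformatted{          affected  unaffected
#'   group 1      a          b
#'   group 2      c          d}
#' conditioning on both margins. The two-sided p-value sums the
#' hypergeometric probabilities of all tables with the same margins
#' whose probability does not exceed that of the observed table
#' (minimum-likelihood method); no chi-square approximation is used.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The p-value in (0, 1]. When all four cells are zero the
#'   test is undefined; 1 is returned with attribute
#'   `degenerate = TRUE`.
#' @examples
#' fisherExact2x2(3, 21, 0, 44)  # 0.040
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0,
            a == floor(a), b == floor(b), c == floor(c), d == floor(d))
  if (a + b + c + d == 0) {
    return(structure(1, degenerate = TRUE))
  }
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  support <- max(0, k - r2):min(k, r1)
  dens <- stats::dhyper(support, r1, r2, k)
  pObs <- stats::dhyper(a, r1, r2, k)
  ## relative tolerance guards against ties lost to floating error
  min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
}

## exact Mann-Whitney U distribution support helpers -------------------

.uStatistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Computes the two-sided p-value of the unpaired rank-sum test. The
#' exact null distribution of the U statistic is used when both groups
#' have at most `exactLimit` observations and the data contain no
#' ties; otherwise the normal approximation with tie correction (and
#' continuity correction) is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact
#'   distribution; the default `NULL` auto-selects as described.
#' @param exactLimit Largest per-group size for the automatic exact
#'   path (default 10).
#' @param correct Apply the continuity correction on the normal path.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' wilcoxonRankSum(1:3, 4:6)  # 0.1, the most extreme of C(6,3) splits
#' @export
wilcoxonRankSum <- function(x, y, exact = NULL, exactLimit = 10L,
                            correct = TRUE) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) {
    exact <- n1 <= exactLimit && n2 <= exactLimit && !ties
  }
  if (exact && ties) {
    stop("exact distribution is unavailable with ties", call. = FALSE)
  }
  u <- .uStatistic(x, y)
  if (exact) {
    ## exact null distribution of U (number of subsets of ranks with a
    ## given rank-sum); dwilcox evaluates the combinatorial recursion
    if (u > n1 * n2 / 2) {
      p <- 2 * sum(stats::dwilcox(ceiling(u):(n1 * n2), n1, n2))
    } else {
      p <- 2 * sum(stats::dwilcox(0:floor(u), n1, n2))
    }
    return(min(1, p))
  }
  n <- n1 + n2
  tied <- table(c(x, y))
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(tied^3 - tied) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all observations identical
  z <- u - mu
  if (correct) z <- z - sign(z) * 0.5
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for a family of `m` tests; kept explicit so the
#' family size is always stated by the caller.
#'
#' @param p Numeric vector of unadjusted p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, p * m)
}
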