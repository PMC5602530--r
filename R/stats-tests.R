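## The cohort statistical battery, implemented in the package: Pearson
## chi-squared (2x2, uncorrected), two-sided Fisher exact (point-probability
## ordering), Mann-Whitney U (exact for small untied samples, otherwise
## normal approximation with tie and continuity corrections), Kruskal-Wallis
## with tie correction, and Pearson correlation with the t-based p-value.
## Results are returned as "htest" objects so they print like base R tests.

.htest <- function(statistic, parameter = NULL, p.value, method,
                   estimate = NULL, data.name = "table") {
  out <- list(statistic = statistic, parameter = parameter,
              p.value = min(max(p.value, 0), 1), method = method,
              estimate = estimate, data.name = data.name)
  class(out) <- "htest"
  out
}

.check2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == 2L) || any(x < 0) || any(x != round(x)))
    stop("need a 2x2 table of nonnegative integer counts")
  storage.mode(x) <- "double"
  x
}

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Uncorrected (no continuity correction) Pearson statistic
#' `sum((O - E)^2 / E)` with 1 degree of freedom and an upper-tail
#' chi-squared p-value. All margins must be positive.
#'
#' @param x 2x2 matrix of counts (rows = exposure levels, columns = rim
#'   status).
#' @return An `htest` with `statistic` (X-squared), `parameter` (df) and
#'   `p.value`.
#' @examples
#' pearsonChi2(matrix(c(34, 22, 20, 7), 2))  # X2 = 1.430, p = 0.232
#' @export
pearsonChi2 <- function(x) {
  x <- .check2x2(x)
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  if (any(rs == 0) || any(cs == 0))
    stop("chi-squared test undefined: zero margin")
  e <- outer(rs, cs) / n
  stat <- sum((x - e)^2 / e)
  .htest(c("X-squared" = stat), c(df = 1),
         pchisq(stat, df = 1, lower.tail = FALSE),
         "Pearson's chi-squared test (2x2, uncorrected)")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' With margins fixed, the two-sided p-value is the sum of hypergeometric
#' point probabilities of every table whose probability does not exceed that
#' of the observed table (point-probability ordering). A degenerate margin
#' yields p = 1.
#'
#' @param x 2x2 matrix of counts.
#' @return An `htest` with the sample odds ratio as `estimate` and the exact
#'   `p.value`.
#' @examples
#' fisherExact2x2(matrix(c(4, 0, 52, 27), 2))$p.value  # 0.299
#' @export
fisherExact2x2 <- function(x) {
  x <- .check2x2(x)
  r1 <- sum(x[1, ]); r2 <- sum(x[2, ]); c1 <- sum(x[, 1])
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- dhyper(support, r1, r2, c1)
  pObs <- dhyper(x[1, 1], r1, r2, c1)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  orEst <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  .htest(NULL, NULL, p,
         "Fisher's exact test (two-sided, point-probability ordering)",
         estimate = c("odds ratio" = orEst))
}

#' Mann-Whitney U test
#'
#' The U statistic is computed from the rank sum of `x` (midranks for ties).
#' When `min(n1, n2) <= exactMaxN` and there are no ties, the exact
#' two-sided p-value is twice the smaller tail of the exact U distribution
#' (capped at 1); otherwise the normal approximation with tie correction and
#' a 0.5 continuity correction is used.
#'
#' @param x,y nonempty numeric samples.
#' @param exactMaxN largest `min(n1, n2)` for which the exact distribution
#'   is used (default 8).
#' @return An `htest` with `statistic` U and `p.value`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(x, y, exactMaxN = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)

  if (!hasTies && min(n1, n2) <= exactMaxN) {
    mid <- n1 * n2 / 2
    p <- if (u == mid) 1 else if (u < mid)
      2 * pwilcox(u, n1, n2) else 2 * pwilcox(n1 * n2 - u, n2, n1)
    method <- "Mann-Whitney U test (exact)"
  } else {
    mu <- n1 * n2 / 2
    tieTerm <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      p <- 2 * pnorm(-abs(z))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  .htest(c(U = u), NULL, min(p, 1), method)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with the standard tie correction, `k - 1` degrees of freedom
#' and an upper-tail chi-squared p-value.
#'
#' @param groups list of at least two nonempty numeric samples.
#' @return An `htest` with `statistic` H, `parameter` df and `p.value`.
#' @examples
#' kruskalWallisH(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 4.571
#' @export
kruskalWallisH <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least two nonempty groups")
  all <- unlist(groups, use.names = FALSE)
  n <- length(all)
  r <- rank(all)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_len(k), sizes)
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
  ties <- table(all)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  .htest(c(H = h), c(df = k - 1),
         pchisq(h, df = k - 1, lower.tail = FALSE),
         "Kruskal-Wallis rank-sum test (tie-corrected)")
}

#' Pearson product-moment correlation with t-based p-value
#'
#' @param x,y numeric samples of equal length, n >= 3, with nonzero
#'   variances.
#' @return An `htest` with `estimate` r, `statistic` t, `parameter` df and
#'   the two-sided `p.value`.
#' @examples
#' pearsonCorrelation(1:4, c(1, 3, 2, 4))$estimate  # r = 0.8
#' @export
pearsonCorrelation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need paired samples with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance sample")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  .htest(c(t = tstat), c(df = df), p, "Pearson's product-moment correlation",
         estimate = c(r = r))
}
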