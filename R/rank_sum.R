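#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' The workhorse two-sample test of the package.  For untied samples with
#' `length(x) + length(y) <= exact_max` the p-value is exact, computed
#' from the full null distribution of the Mann-Whitney U statistic (a
#' dynamic program over rank subsets); otherwise the normal approximation
#' with midrank tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (`x` tends to
#'   exceed `y`) or `"less"`.
#' @param exact_max Largest total sample size for the exact path
#'   (default 30; the exact path also requires the pooled sample to be
#'   tie-free).
#' @return List with elements `U` (Mann-Whitney U of `x`), `p`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, exact
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          exact_max = 30L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n <= exact_max) {
    cdf <- cumsum(.u_null_counts(n1, n2))  # P(U <= u) * choose(n, n1)
    tot <- cdf[length(cdf)]
    p_le <- cdf[U + 1] / tot
    p_ge <- if (U == 0) 1 else 1 - cdf[U] / tot
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(list(U = U, p = p, method = "exact"))
  }

  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  sigma <- sqrt(n1 * n2 / 12 *
                ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1))))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal"))
  z <- U - mu
  corr <- switch(alternative,
                 two.sided = sign(z) * 0.5,
                 greater = 0.5,
                 less = -0.5)
  z <- (z - corr) / sigma
  p <- switch(alternative,
              two.sided = min(1, 2 * min(stats::pnorm(z),
                                         stats::pnorm(z, lower.tail = FALSE))),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(U = U, p = p, method = "normal")
}

# Null counts of the Mann-Whitney U statistic for untied samples:
# number of ways to choose n1 of the ranks 1..n1+n2 yielding each U in
# 0..n1*n2.  Classic subset-sum dynamic program.
.u_null_counts <- function(n1, n2) {
  n <- n1 + n2
  smax <- sum((n2 + 1):n)        # max rank sum of the x-sample
  dp <- vector("list", n1 + 1L)
  dp[[1L]] <- c(1, numeric(smax))  # dp[[k+1]][s+1] = #subsets size k, sum s
  for (k in seq_len(n1)) dp[[k + 1L]] <- numeric(smax + 1L)
  for (i in seq_len(n)) {
    for (k in rev(seq_len(min(i, n1)))) {
      dp[[k + 1L]][(i + 1L):(smax + 1L)] <-
        dp[[k + 1L]][(i + 1L):(smax + 1L)] +
        dp[[k]][1L:(smax + 1L - i)]
    }
  }
  w <- dp[[n1 + 1L]]
  smin <- n1 * (n1 + 1) / 2
  # U = ranksum - smin, spans 0..n1*n2
  w[(smin + 1L):(smin + n1 * n2 + 1L)]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validated front-end to the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
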