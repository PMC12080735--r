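#' Wilcoxon signed-rank test for paired samples
#'
#' Classical signed-rank test: zero differences are dropped, tied absolute
#' differences receive average ranks, and the statistic is the sum of ranks
#' of positive differences. For `n <= exact_limit` effective pairs the
#' two-sided p-value is exact, computed from the full null distribution of
#' the rank sum (equivalent to enumerating all sign assignments, but via a
#' convolution over ranks so ties cost nothing extra). Above the limit a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @param exact_limit Largest n for which the exact distribution is used
#'   (default 25).
#' @return A one-row tibble: `statistic` (V, rank sum of positive
#'   differences), `p_value` (two-sided), `n_effective` (non-zero pairs),
#'   `method` ("exact" or "normal").
#' @examples
#' wilcoxon_signed_rank(c(1, 3, 5, 7), c(0, 1, 2, 3))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need at least 2 pairs.")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all differences are zero; p-value is 1.")
    return(tibble(statistic = 0, p_value = 1, n_effective = 0L,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(statistic = v, p_value = p, n_effective = as.integer(n),
         method = method)
}

# Exact two-sided p for rank sum `v` given signed ranks `r` (average ranks
# allowed). Doubling the ranks makes all masses land on integers; the null
# distribution is built by convolving each rank in/out with probability 1/2.
signed_rank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1) # index s+1 holds #assignments with sum s
  counts[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), counts[seq_len(total + 1 - rr)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(probs[seq_len(v2 + 1)])
  p_ge <- sum(probs[seq(v2 + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n = length(x))
}
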