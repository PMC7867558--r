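#' Monte-Carlo power of the paired signed-rank test on discrete differences
#'
#' For each replicate, draws `n` differences from `dist` and applies the
#' same signed-rank test used by the crossover analysis (two-sided, zero
#' differences dropped, tie-corrected); power is the fraction of replicates
#' with `p < alpha`. Deterministic for a given seed.
#'
#' @param dist A [discrete_distribution()] of paired differences.
#' @param n Pairs per simulated study (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param n_sims Number of replicates (default 10000).
#' @param seed Integer seed.
#' @return An object of class `power_result`: list with `power`, `se`
#'   (Monte-Carlo standard error), `rejections`, `n_sims`, `n`, `alpha`.
#' @export
simulate_power <- function(dist, n, alpha = 0.05, n_sims = 10000, seed = 1L) {
  stopifnot(inherits(dist, "discrete_distribution"))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  draws <- with_seed(seed,
    matrix(dist$support[sample.int(length(dist$support), n * n_sims,
                                   replace = TRUE,
                                   prob = dist$probabilities)], nrow = n))
  rej <- sum(apply(draws, 2L, function(d) signed_rank_p(d)$p) < alpha)
  p_hat <- rej / n_sims
  structure(list(power = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_sims),
                 rejections = rej, n_sims = n_sims, n = n, alpha = alpha),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> power %.3f (MC SE %.4f), %d/%d rejections at alpha %g, n = %d\n",
              x$power, x$se, x$rejections, x$n_sims, x$alpha, x$n))
  invisible(x)
}

# Enumerate all count vectors (k_1, ..., k_s) with sum n.
compositions <- function(n, s) {
  if (s == 1L) return(matrix(n, nrow = 1L))
  out <- list()
  for (k in 0:n) {
    rest <- compositions(n - k, s - 1L)
    out[[length(out) + 1L]] <- cbind(k, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exact power of the signed-rank test by enumeration
#'
#' Sums the probability of every outcome multiset of `n` draws whose
#' two-sided signed-rank p-value (computed by the identical test
#' implementation used for simulation and analysis) is below `alpha`.
#' Feasible for small supports and sample sizes; the enumeration is
#' refused when `|support|^n > 1e7`.
#'
#' @param dist A [discrete_distribution()].
#' @param n Number of differences per study.
#' @param alpha Significance level.
#' @return Exact rejection probability in [0, 1].
#' @export
exact_power <- function(dist, n, alpha = 0.05) {
  stopifnot(inherits(dist, "discrete_distribution"))
  s <- length(dist$support)
  if (s^n > 1e7)
    stop("|support|^n exceeds 1e7; use simulate_power() instead",
         call. = FALSE)
  counts <- compositions(n, s)
  lfact <- lgamma(n + 1)
  total <- 0
  lp <- log(ifelse(dist$probabilities > 0, dist$probabilities, 1))
  for (i in seq_len(nrow(counts))) {
    k <- counts[i, ]
    if (any(k > 0 & dist$probabilities == 0)) next
    d <- rep(dist$support, k)
    if (signed_rank_p(d)$p < alpha) {
      logprob <- lfact - sum(lgamma(k + 1)) + sum(k * lp)
      total <- total + exp(logprob)
    }
  }
  min(max(total, 0), 1)   # guard against summed-exponential rounding
}

#' Median of a discrete distribution (midpoint convention)
#'
#' The 0.5 quantile; when the cumulative distribution hits exactly 0.5 at a
#' support point, the median is the midpoint between that point and the
#' next, so integer-valued differences can have a half-integer median.
#'
#' @param dist A [discrete_distribution()].
#' @return Numeric scalar.
#' @export
#' @examples
#' distribution_median(discrete_distribution(1:2, c(0.5, 0.5)))  # 1.5
distribution_median <- function(dist) {
  stopifnot(inherits(dist, "discrete_distribution"))
  cdf <- cumsum(dist$probabilities)
  i <- which(cdf >= 0.5 - 1e-12)[1L]
  if (abs(cdf[i] - 0.5) <= 1e-12 && i < length(dist$support))
    (dist$support[i] + dist$support[i + 1L]) / 2
  else
    dist$support[i]
}
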