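#' Derive a reproducible child seed from a master seed and a tag
#'
#' Module- and subject-level seeds are derived by stable hashing of
#' (master seed, tag) so that adding a consumer of randomness never perturbs
#' the draws of earlier ones. The hash is a Lehmer-style multiplicative mix
#' modulo the Mersenne prime 2^31 - 1; all intermediates stay below 2^53 so
#' the arithmetic is exact in doubles.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer (e.g. "task_sim/S03/OFF").
#' @return an integer in \[1, 2^31 - 2\] suitable for [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647
  h <- (abs(seed) %% m) * 69069 %% m
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Ex-Gaussian random deviates
#'
#' Sum of a Normal(mu, sigma) and an independent Exponential(mean tau)
#' variate; the standard positively skewed model for reaction times.
#'
#' @param n number of deviates.
#' @param mu,sigma Gaussian component mean and sd (sigma > 0), ms.
#' @param tau exponential component mean (tau >= 0), ms.
#' @return numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau >= 0)
  x <- rnorm(n, mu, sigma)
  if (tau > 0) x <- x + rexp(n, rate = 1 / tau)
  x
}

# Normal(mean, sd) truncated below at 0, by inverse-CDF sampling.
rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(pmax(rep(mean, n), 0))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

# clip x into [bounds[1], bounds[2]]
clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

stop_invalid <- function(...) {
  stop(structure(class = c("stopsignal_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
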