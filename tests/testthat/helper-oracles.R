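# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Ex-Gaussian CDF, closed form (independent of the package's sampler):
# F(t) = Phi(z) - exp(sigma^2/(2 tau^2) - (t - mu)/tau) * Phi(z - sigma/tau)
pexgauss_oracle <- function(t, mu, sigma, tau) {
  z <- (t - mu) / sigma
  pnorm(z) - exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
    pnorm(z - sigma / tau)
}

# Fixed-point solver for the random-effects Dirichlet posterior, written
# directly from the update equations and iterated to 1e-12; checks rfx_bms.
rfx_fixed_point_oracle <- function(lnE, prior = 1, iters = 10000) {
  K <- ncol(lnE)
  alpha <- rep(prior, K) + nrow(lnE) / K
  for (i in seq_len(iters)) {
    u <- exp(sweep(lnE, 2, digamma(alpha) - digamma(sum(alpha)), `+`))
    g <- u / rowSums(u)
    new <- rep(prior, K) + colSums(g)
    if (max(abs(new - alpha)) < 1e-12) return(new)
    alpha <- new
  }
  alpha
}

# small session/template builders used by several files
tiny_config <- function(...) task_config(n_blocks = 1, trials_per_block = 50, ...)

tiny_templates <- function(n_channels = 16) erp_templates(n_channels = n_channels)

# hand-built session wrapper around a bare trial table
make_session <- function(trials, subject = "S01", condition = "OFF") {
  structure(list(subject_id = subject, condition = condition, trials = trials,
                 config = NULL, params = NULL), class = "sst_session")
}
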