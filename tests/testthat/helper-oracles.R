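# Independent oracles and fixture builders used across the suite.

# Sequential one-dimensional Kalman fusion: starting from the agent's own
# Gaussian (mu0, s0), absorb each neighbor's opinion as an independent
# scalar measurement. Algebraically independent of the package's
# vectorized precision-sum implementation.
kalman_fuse <- function(mu0, s0, mu_nb, s_nb) {
  mu <- mu0
  s <- s0
  for (j in seq_along(mu_nb)) {
    gain <- s / (s + s_nb[j])
    mu <- mu + gain * (mu_nb[j] - mu)
    s <- (1 - gain) * s
  }
  c(mu = mu, sigma2 = s)
}

# A random closed neighborhood as a star graph: agent 1 in the center with
# `k` neighbors, log-uniform variances so scales span several decades.
random_neighborhood <- function(k = sample(1:8, 1)) {
  list(
    g = hetcon::make_star_graph(k + 1),
    b = hetcon::belief_state(
      mu = stats::rnorm(k + 1, 0, 5),
      sigma2 = exp(stats::runif(k + 1, log(1e-2), log(1e2)))
    )
  )
}

# Population standard deviation, for degree-heterogeneity cross-checks.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
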