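# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: moments come from exhaustive enumeration of
# binomial outcomes, likelihood maxima from dense grid search, and the HMM
# forward value from brute-force summation over all hidden-state paths.

# Exhaustively enumerate the sampling distribution of the estimator's
# numerator D and bias-corrected denominator V for a short population
# trajectory `freqs` observed with constant sample size `ns` at constant
# step `dt`. Returns exact moments.
enumerate_DV_moments <- function(freqs, dt, ns, mu) {
  kk <- length(freqs) - 1
  counts <- do.call(expand.grid, rep(list(0:ns), kk + 1))
  pr <- rep(1, nrow(counts))
  for (j in seq_len(kk + 1)) {
    pr <- pr * dbinom(counts[[j]], ns, freqs[j])
  }
  xh <- as.matrix(counts) / ns
  lead <- seq_len(kk)
  D <- xh[, kk + 1] - xh[, 1] - mu * dt * rowSums(1 - 2 * xh[, lead, drop = FALSE])
  V <- (ns / (ns - 1)) * dt * rowSums((xh * (1 - xh))[, lead, drop = FALSE])
  m <- function(z) sum(pr * z)
  list(
    mean_D = m(D), mean_V = m(V),
    var_D = m(D^2) - m(D)^2,
    cov_DV = m(D * V) - m(D) * m(V),
    var_V = m(V^2) - m(V)^2
  )
}

# Exact expectation of the corrected sample variance (ns/(ns-1)) * xh(1-xh)
# under Binomial(ns, x) sampling, by full enumeration.
enumerate_corrected_variance_mean <- function(x, ns) {
  cc <- 0:ns
  xh <- cc / ns
  sum(dbinom(cc, ns, x) * (ns / (ns - 1)) * xh * (1 - xh))
}

# Brute-force HMM likelihood: sum over all grid-state paths of transition
# times emission products (small K and D only).
brute_force_hmm_lik <- function(s, obs, N, mu, D) {
  grid <- frequency_grid(D)
  m <- grid$midpoint
  dts <- diff(obs$generation)
  tms <- lapply(dts, function(dt) mpl_transition_matrix(grid, s, mu, N, dt))
  i0 <- min(D, floor(obs$mutant_count[1] / obs$sample_size[1] * D) + 1)
  kk <- length(dts)
  paths <- do.call(expand.grid, rep(list(seq_len(D)), kk))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    p <- 1
    prev <- i0
    for (k in seq_len(kk)) {
      p <- p * tms[[k]][prev, path[k]] *
        dbinom(obs$mutant_count[k + 1], obs$sample_size[k + 1], m[path[k]])
      prev <- path[k]
    }
    tot <- tot + p
  }
  tot
}

# Dense grid argmax of the Gaussian path log-likelihood.
grid_argmax_loglik <- function(freqs, times, N, mu,
                               lo = -0.5, hi = 0.5, n = 20001) {
  svals <- seq(lo, hi, length.out = n)
  ll <- mpl_loglik(svals, freqs, times, N = N, mu = mu)
  svals[which.max(ll)]
}

# Numeric-integration KL divergence of a standardised Exp(1) sample's
# population density from N(0, 1): closed form -H[Exp] + cross-entropy.
kl_exponential_oracle <- function() {
  # f(x) = exp(-(x+1)) on (-1, Inf); log f - log phi written out so the
  # integrand decays cleanly instead of producing 0 * log(0)
  integrand <- function(x) {
    exp(-(x + 1)) * (x^2 / 2 - x - 1 + 0.5 * log(2 * pi))
  }
  integrate(integrand, -1, Inf)$value
}

# A small deterministic observed trajectory used by io / estimator tests.
make_test_obs <- function(seed = 42, generations = 150, dt = 10, ns = 30,
                          s = 0.03) {
  traj <- sim_trajectory(s = s, mu = 1e-3, x0 = 0.1,
                         generations = generations, model = "det_exact")
  observe(traj, dt = dt, ns = ns, seed = seed)
}
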