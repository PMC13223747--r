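#' Uniform frequency grid for the HMM benchmark estimator
#'
#' Partitions `[0, 1]` into `D` equal bins whose midpoints
#' `m_i = (i - 0.5) / D` serve as the hidden states of the HMM. With the
#' default `D = 100` no midpoint touches a boundary, so every state has a
#' positive allele variance.
#'
#' @param D Number of bins (default 100).
#' @return A tibble with columns `bin`, `lower`, `upper`, `midpoint`.
#' @export
frequency_grid <- function(D = 100) {
  stopifnot(D >= 2)
  tibble::tibble(bin = seq_len(D),
                 lower = (seq_len(D) - 1) / D,
                 upper = seq_len(D) / D,
                 midpoint = (seq_len(D) - 0.5) / D)
}

#' Grid-discretised Gaussian transition matrix
#'
#' Discretises the Gaussian path-likelihood transition density onto the
#' frequency grid: entry `(i, j)` is proportional to the density of
#' reaching midpoint `m_j` from `m_i` after `dt` generations, i.e. a normal
#' with mean `m_i + dt (s v_i + mu (1 - 2 m_i))` and variance
#' `dt v_i / N`. Each row is renormalised to sum to one, since the
#' discretised density is not itself a probability vector.
#'
#' @param grid A grid tibble from [frequency_grid()], or an integer `D`.
#' @param s Selection coefficient.
#' @param mu Mutation probability per generation.
#' @param N Population size.
#' @param dt Time step between the two sampled generations.
#'
#' @return A row-stochastic `D x D` matrix.
#' @export
mpl_transition_matrix <- function(grid, s, mu, N, dt) {
  if (!is.data.frame(grid)) grid <- frequency_grid(grid)
  m <- grid$midpoint
  v <- m * (1 - m)
  mean_to <- m + dt * (s * v + mu * (1 - 2 * m))
  sd_to <- sqrt(dt * v / N)
  dens <- stats::dnorm(outer(rep(1, length(m)), m), mean = mean_to,
                       sd = sd_to)
  sweep(dens, 1, rowSums(dens), "/")
}

#' Binomial emission probabilities over grid states
#'
#' The probability of observing `count` mutant alleles in a sample of size
#' `size` given that the hidden population frequency sits at each grid
#' midpoint.
#'
#' @inheritParams mpl_transition_matrix
#' @param count Observed mutant allele count.
#' @param size Sample size.
#'
#' @return A vector of length `D` (one probability per state).
#' @export
emission_probs <- function(grid, count, size) {
  if (!is.data.frame(grid)) grid <- frequency_grid(grid)
  stats::dbinom(count, size, grid$midpoint)
}

#' HMM log-likelihood of an observed trajectory
#'
#' The forward algorithm over the frequency grid: hidden states evolve by
#' the Gaussian path-likelihood transitions, observations are binomial
#' counts. The recursion is scaled at each step (normalising the forward
#' vector and accumulating log normalisers), which is algebraically the
#' log-space recursion and cannot underflow. The initial state is a point
#' mass on the bin containing the first observed frequency (the likelihood
#' conditions on the initial frequency, of which only the observation is
#' available); a uniform prior over states is available as an alternative.
#' Heterogeneous sampling steps are supported by recomputing the transition
#' matrix per step.
#'
#' @param s Selection coefficient at which to evaluate the likelihood.
#' @param obs Observed trajectory (columns `generation`, `sample_size`,
#'   `mutant_count`), at least two time points.
#' @param N Population size.
#' @param mu Mutation probability per generation.
#' @param D Number of grid bins.
#' @param init_prior `"point"` (default) or `"uniform"`. The likelihood
#'   conditions on the initial frequency; with real data only its
#'   observation is available, so `"point"` places the initial state in the
#'   bin containing the first observed frequency.
#' @param x0 Optional known initial population frequency (e.g. in
#'   simulation studies): the initial state is then the bin containing
#'   `x0`, overriding `init_prior`.
#'
#' @return The log-likelihood (scalar).
#' @export
hmm_loglik <- function(s, obs, N, mu = 0, D = 100,
                       init_prior = c("point", "uniform"), x0 = NULL) {
  init_prior <- match.arg(init_prior)
  obs <- validate_observed(obs)
  if (nrow(obs) < 2) {
    rlang::abort("need at least two observed time points.")
  }
  grid <- frequency_grid(D)
  m <- grid$midpoint
  dts <- diff(obs$generation)
  same_dt <- length(unique(dts)) == 1
  if (same_dt) {
    tm <- mpl_transition_matrix(grid, s, mu, N, dts[1])
  }
  if (!is.null(x0) || init_prior == "point") {
    start <- if (!is.null(x0)) x0 else obs$mutant_count[1] / obs$sample_size[1]
    alpha <- numeric(D)
    alpha[min(D, floor(start * D) + 1)] <- 1
  } else {
    alpha <- rep(1 / D, D)
  }
  ll <- 0
  for (k in seq_along(dts)) {
    if (!same_dt) {
      tm <- mpl_transition_matrix(grid, s, mu, N, dts[k])
    }
    alpha <- as.vector(alpha %*% tm) *
      stats::dbinom(obs$mutant_count[k + 1], obs$sample_size[k + 1], m)
    sc <- sum(alpha)
    if (sc <= 0) {
      return(-Inf)
    }
    ll <- ll + log(sc)
    alpha <- alpha / sc
  }
  ll
}

#' Maximum-likelihood selection coefficient from the HMM
#'
#' Maximises [hmm_loglik()] over `s` with the one-dimensional Nelder-Mead
#' simplex (tolerance `1e-4` on both the parameter and the objective),
#' initialised at the closed-form MPL estimate of the observed data (or 0
#' when that estimate is undefined). The fit is deterministic given the
#' inputs.
#'
#' @inheritParams hmm_loglik
#' @param init_s Starting value; default the MPL estimate of `obs`.
#' @param tol Nelder-Mead tolerance.
#'
#' @return An object of class `"hmm_fit"`: list with `s_ls`, `loglik`,
#'   `n_evals`, `converged`, plus the settings used.
#' @export
#' @examples
#' traj <- sim_trajectory(s = 0.02, model = "det_exact", generations = 150)
#' obs <- observe(traj, dt = 10, ns = 20, seed = 1)
#' fit_s_ls(obs, N = 1000, mu = 1e-3)
fit_s_ls <- function(obs, N, mu = 0, D = 100, tol = 1e-4, init_s = NULL,
                     init_prior = c("point", "uniform"), x0 = NULL) {
  init_prior <- match.arg(init_prior)
  obs <- validate_observed(obs)
  if (is.null(init_s)) {
    init_s <- tryCatch(estimate_s(obs, mu = mu)$s_hat, error = function(e) 0)
  }
  opt <- stats::optim(
    init_s,
    function(s) -hmm_loglik(s, obs, N = N, mu = mu, D = D,
                            init_prior = init_prior, x0 = x0),
    method = "Nelder-Mead",
    control = list(abstol = tol, reltol = tol, warn.1d.NelderMead = FALSE)
  )
  structure(
    list(s_ls = opt$par, loglik = -opt$value,
         n_evals = unname(opt$counts["function"]),
         converged = opt$convergence == 0,
         D = D, tol = tol, N = N, mu = mu, init_prior = init_prior),
    class = "hmm_fit"
  )
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Grid-HMM selection-coefficient estimate\n")
  cat(sprintf("  s_ls      : % .6f\n", x$s_ls))
  cat(sprintf("  loglik    : %.4f  (%d evaluations%s)\n", x$loglik,
              x$n_evals, if (x$converged) ", converged" else ""))
  cat(sprintf("  grid bins : %d, N = %g, mu = %g, init = %s\n",
              x$D, x$N, x$mu, x$init_prior))
  invisible(x)
}

#' @export
tidy.hmm_fit <- function(x, ...) {
  tibble::tibble(term = "s", estimate = x$s_ls)
}

#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(s_ls = x$s_ls, loglik = x$loglik, n_evals = x$n_evals,
                 converged = x$converged, D = x$D, N = x$N, mu = x$mu)
}
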