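#' Sampling-noise moments of the estimator's numerator and denominator
#'
#' Exact moments of the numerator `D` (net frequency change minus mutation
#' flux) and bias-corrected denominator `V` of the MPL estimate under
#' independent binomial sampling of a fixed population trajectory, assuming
#' a constant sample size `ns` and constant sampling step `dt`:
#' \deqn{Var[D] = \frac{1}{n_s}\left[v(t_K) + v(t_0) - 4\mu\,dt\,v(t_0)
#'   + 4\mu^2 dt\, V\right],}
#' \deqn{Cov[D, V] = -\frac{dt}{n_s}\left[v(t_0)(1 - 2x(t_0))
#'   - 2\mu\,dt \sum_k v(t_k)(1 - 2x(t_k))\right],}
#' \deqn{Var[V] = \frac{dt}{n_s}\left[V - \left(4 - \frac{2}{n_s - 1}\right)
#'   dt \sum_k v^2(t_k)\right].}
#' These expressions are exact (not asymptotic) for the binomial sampling
#' model with the `ns/(ns-1)` correction applied; sums run over
#' `k = 0, ..., K-1`.
#'
#' @param freqs Population frequencies at the `K + 1` sampling times.
#' @param dt Constant sampling step (generations).
#' @param ns Constant sample size per time point (`>= 2`).
#' @param mu Mutation probability per generation.
#'
#' @return A scalar variance or covariance.
#' @name sampling_moments
NULL

#' @rdname sampling_moments
#' @export
var_D <- function(freqs, dt, ns, mu = 0) {
  k <- length(freqs) - 1
  v <- freqs * (1 - freqs)
  bigv <- integrated_variance(freqs, dt)
  (v[k + 1] + v[1] - 4 * mu * dt * v[1] + 4 * mu^2 * dt * bigv) / ns
}

#' @rdname sampling_moments
#' @export
cov_DV <- function(freqs, dt, ns, mu = 0) {
  k <- length(freqs) - 1
  v <- freqs * (1 - freqs)
  lead <- seq_len(k)
  -dt / ns * (v[1] * (1 - 2 * freqs[1]) -
                2 * mu * dt * sum(v[lead] * (1 - 2 * freqs[lead])))
}

#' @rdname sampling_moments
#' @export
var_V <- function(freqs, dt, ns) {
  stopifnot(ns >= 2)
  k <- length(freqs) - 1
  v <- freqs * (1 - freqs)
  lead <- seq_len(k)
  bigv <- integrated_variance(freqs, dt)
  dt / ns * (bigv - (4 - 2 / (ns - 1)) * (dt * sum(v[lead]^2)))
}

#' First-order mean of the estimator under limited sampling
#'
#' The leading term of the Taylor expansion of `E[D/V]` about the means of
#' numerator and denominator: the MPL estimate of the population trajectory
#' itself. Exact recovery of the generating coefficient holds for the
#' linearised deterministic model; for the exact model it holds to
#' second order in `s` and `mu`.
#'
#' @inheritParams sampling_moments
#' @return The analytic estimator mean (scalar).
#' @export
analytic_mean <- function(freqs, dt, mu = 0) {
  k <- length(freqs) - 1
  s_mpl(freqs, seq(0, k) * dt, mu = mu)
}

#' Sampling-only variance of the estimator (first-order theory)
#'
#' Combines the exact numerator/denominator moments through the first-order
#' variance expansion of the ratio `D/V`:
#' \deqn{Var[\hat{s}] = \frac{Var[D]}{V^2}
#'   - 2\hat{s}_{MPL}\frac{Cov[D,V]}{V^2}
#'   + \hat{s}_{MPL}^2\frac{Var[V]}{V^2},}
#' with the analytic mean standing in for the ratio of means. Scales as
#' `O(1/(ns V^2))`.
#'
#' @inheritParams sampling_moments
#' @return The approximate sampling-only variance of the estimate.
#' @export
var_s_sampling <- function(freqs, dt, ns, mu = 0) {
  bigv <- integrated_variance(freqs, dt)
  stopifnot(bigv > 0)
  smpl <- analytic_mean(freqs, dt, mu)
  (var_D(freqs, dt, ns, mu) - 2 * smpl * cov_DV(freqs, dt, ns, mu) +
     smpl^2 * var_V(freqs, dt, ns)) / bigv^2
}

#' Cramer-Rao lower bound on the drift-only variance
#'
#' With perfect sampling, the Fisher information of the Gaussian path
#' likelihood is `N * V`, so no unbiased estimator can beat a variance of
#' `1 / (N V)`. Simulation shows the bound is close to attained for the MPL
#' estimate when `N` is not small.
#'
#' @param N Population size.
#' @param V Integrated variance of the (mean) trajectory.
#' @return The bound `1 / (N * V)`.
#' @export
#' @examples
#' crlb_drift(1000, 10) # 1e-4
crlb_drift <- function(N, V) {
  stopifnot(N > 0, V > 0)
  1 / (N * V)
}

#' Total estimator variance under sampling and drift
#'
#' The additive decomposition: sampling-only variance evaluated on the
#' deterministic mean trajectory plus the drift-only component approximated
#' by its (tight) Cramer-Rao bound `1/(N V)`. The two noise sources behave
#' as uncorrelated, so the sum tracks the joint-noise Monte-Carlo variance.
#'
#' @inheritParams sampling_moments
#' @param N Population size.
#' @return Approximate total variance of the estimate.
#' @export
var_total <- function(freqs, dt, ns, N, mu = 0) {
  var_s_sampling(freqs, dt, ns, mu) +
    crlb_drift(N, integrated_variance(freqs, dt))
}

#' Analytic performance report for a trajectory
#'
#' Evaluates the full variance theory on a population trajectory sampled at
#' a constant step: numerator/denominator moments, the sampling-only
#' variance, the drift CRLB, their sum, the integrated variance and the
#' analytic mean.
#'
#' @param traj Trajectory tibble (columns `generation`, `frequency`); the
#'   deterministic mean trajectory in typical use.
#' @param dt Constant sampling step; frequencies are taken at generations
#'   `0, dt, 2 dt, ...`.
#' @param ns Constant sample size per time point.
#' @param N Population size.
#' @param mu Mutation probability per generation.
#'
#' @return A one-row tibble with columns `mean_s`, `var_D`, `cov_DV`,
#'   `var_V`, `var_s_sampling`, `crlb_drift`, `var_total`, `V`.
#' @export
#' @examples
#' traj <- sim_trajectory(model = "det_exact", generations = 450)
#' theory_report(traj, dt = 10, ns = 20, N = 1000, mu = 1e-3)
theory_report <- function(traj, dt, ns, N, mu = 0) {
  times <- seq(min(traj$generation), max(traj$generation), by = dt)
  x <- traj$frequency[match(times, traj$generation)]
  if (anyNA(x)) {
    rlang::abort("trajectory does not contain every multiple of `dt`.")
  }
  bigv <- integrated_variance(x, dt)
  tibble::tibble(
    mean_s = analytic_mean(x, dt, mu),
    var_D = var_D(x, dt, ns, mu),
    cov_DV = cov_DV(x, dt, ns, mu),
    var_V = var_V(x, dt, ns),
    var_s_sampling = var_s_sampling(x, dt, ns, mu),
    crlb_drift = crlb_drift(N, bigv),
    var_total = var_total(x, dt, ns, N, mu),
    V = bigv
  )
}

#' Gaussian approximation to the estimator distribution
#'
#' For long polymorphic trajectories the estimate is asymptotically Gaussian
#' (central limit theorem applied to the denominator plus the Gaussian-ratio
#' approximation). Returns the mean and variance of the approximating
#' normal: the analytic mean and the sampling-only variance of the supplied
#' trajectory.
#'
#' @inheritParams sampling_moments
#' @return A one-row tibble with columns `mean` and `variance`.
#' @export
gaussian_approx <- function(freqs, dt, ns, mu = 0) {
  tibble::tibble(mean = analytic_mean(freqs, dt, mu),
                 variance = var_s_sampling(freqs, dt, ns, mu))
}

#' Kullback-Leibler divergence of a standardised sample from N(0, 1)
#'
#' Standardises the sample to zero mean and unit variance, bins it with
#' Scott's-rule histogram bins, and computes the discrete divergence of the
#' empirical bin masses from the corresponding normal bin probabilities.
#' Empty bins contribute zero.
#'
#' @param samples Numeric vector of estimates (length >= 100 recommended).
#' @return The divergence estimate in nats (non-negative up to
#'   discretisation error).
#' @export
kl_to_standard_normal <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  stopifnot(n >= 10)
  z <- (samples - mean(samples)) / stats::sd(samples)
  h <- 3.49 * n^(-1 / 3) # Scott's rule; sd = 1 after standardisation
  breaks <- seq(floor(min(z) / h) * h, ceiling(max(z) / h) * h + h, by = h)
  p <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE),
                nbins = length(breaks) - 1) / n
  # bin masses under N(0,1); far-tail bins via the matching tail of pnorm
  # so the differences do not cancel to zero
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  q <- ifelse(lo >= 0,
              stats::pnorm(lo, lower.tail = FALSE) -
                stats::pnorm(hi, lower.tail = FALSE),
              stats::pnorm(hi) - stats::pnorm(lo))
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' Minimum detectable selection coefficient
#'
#' The smallest selection coefficient detectable at the 5% significance
#' level under the Gaussian approximation: the fixed point of
#' `var_total(s) = (s / 2)^2`, where the total variance is evaluated on the
#' exact deterministic trajectory generated *at that candidate `s`* (the
#' integrated variance depends on `s`). The root is located by scanning a
#' log-spaced grid for the first sign change (the full variance expression
#' can cross the parabola again at very strong selection) and then
#' bisecting within that subinterval.
#'
#' @param N Population size.
#' @param ns Sample size per time point.
#' @param dt Sampling step (generations).
#' @param T Trajectory length in generations (a multiple of `dt`).
#' @param x0 Initial mutant allele frequency.
#' @param mu Mutation probability per generation.
#' @param lower,upper Bracket for the candidate coefficient.
#' @param tol Bisection tolerance on the root.
#'
#' @return The minimum detectable selection coefficient (scalar).
#' @export
#' @examples
#' min_detectable_s(N = 1000, ns = 20, dt = 10, T = 150)
min_detectable_s <- function(N, ns = 20, dt = 10, T = 450, x0 = 0.1,
                             mu = 1e-3, lower = 1e-4, upper = 1,
                             tol = 1e-5) {
  stopifnot(T %% dt == 0, T >= dt)
  f <- function(s) {
    traj <- sim_trajectory(s = s, mu = mu, x0 = x0, generations = T,
                           model = "det_exact")
    x <- traj$frequency[seq(1, T + 1, by = dt)]
    var_total(x, dt, ns, N, mu) - (s / 2)^2
  }
  grid <- exp(seq(log(lower), log(upper), length.out = 80))
  fv <- vapply(grid, f, numeric(1))
  i <- which(fv[-length(fv)] >= 0 & fv[-1] < 0)
  if (length(i) == 0) {
    rlang::abort(sprintf(
      "no detection threshold in (%g, %g): objective is %g at the lower and %g at the upper end.",
      lower, upper, fv[1], fv[length(fv)]))
  }
  i <- i[1]
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
}
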