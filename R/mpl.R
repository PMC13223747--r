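#' Integrated allele variance along a trajectory
#'
#' The precision-determining quantity `V = sum_k dt_k * x(t_k)(1 - x(t_k))`,
#' summed over the first `K` of the `K + 1` time points (the final point is
#' excluded, mirroring the estimator's denominator).
#'
#' @param freqs Frequencies at the `K + 1` sampling times.
#' @param dts Time steps `dt_k = t_{k+1} - t_k` (length `K`), or a scalar
#'   constant step.
#'
#' @return Non-negative scalar `V` in units of variance x generations.
#' @export
#' @examples
#' integrated_variance(rep(0.5, 4), 10) # 7.5
integrated_variance <- function(freqs, dts) {
  k <- length(freqs) - 1
  stopifnot(k >= 1)
  dts <- rep_len(dts, k)
  v <- freqs * (1 - freqs)
  sum(dts * v[seq_len(k)])
}

#' Closed-form MPL selection-coefficient estimator (population frequencies)
#'
#' The maximum-likelihood selection coefficient under the Gaussian path
#' likelihood of the Wright-Fisher diffusion: the net frequency change minus
#' the mutation flux, divided by the integrated variance,
#' \deqn{\hat{s} = \frac{x(t_K) - x(t_0) - \mu \sum_k \Delta t_k (1 - 2 x(t_k))}
#'                     {\sum_k \Delta t_k x(t_k)(1 - x(t_k))}.}
#' Applied to population (noise-free) frequencies; see [estimate_s()] for
#' the bias-corrected version on sampled counts.
#'
#' @param freqs Population frequencies at the sampling times.
#' @param times Strictly increasing sampling generations (same length).
#' @param mu Mutation probability per generation.
#'
#' @return The estimated selection coefficient (scalar).
#' @export
#' @examples
#' traj <- sim_trajectory(s = 0.02, mu = 1e-3, x0 = 0.1,
#'                        generations = 450, model = "det_linear")
#' s_mpl(traj$frequency, traj$generation, mu = 1e-3) # recovers 0.02
s_mpl <- function(freqs, times, mu = 0) {
  stopifnot(length(freqs) == length(times), length(freqs) >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("`times` must be strictly increasing.")
  }
  k <- length(freqs) - 1
  dts <- diff(times)
  v <- freqs * (1 - freqs)
  denom <- sum(dts * v[seq_len(k)])
  if (denom <= 0) {
    rlang::abort("monomorphic trajectory: integrated variance is zero.")
  }
  num <- freqs[k + 1] - freqs[1] - mu * sum(dts * (1 - 2 * freqs[seq_len(k)]))
  num / denom
}

# Vectorised estimator core: rows of `xh` are replicate observed-frequency
# trajectories at common `times`; `sizes` is a vector (per time point) or a
# matrix matching `xh`. Returns the per-replicate estimate, NA where the
# denominator vanishes (replicate uninformative).
shat_matrix <- function(xh, sizes, times, mu = 0, bias_correction = TRUE) {
  k <- ncol(xh) - 1
  dts <- diff(times)
  if (!is.matrix(sizes)) {
    sizes <- matrix(sizes, nrow(xh), ncol(xh), byrow = TRUE)
  }
  vh <- xh * (1 - xh)
  fac <- if (bias_correction) sizes / (sizes - 1) else 1
  lead <- seq_len(k)
  num <- xh[, k + 1] - xh[, 1] -
    mu * as.vector((1 - 2 * xh[, lead, drop = FALSE]) %*% dts)
  den <- as.vector((vh[, lead, drop = FALSE] *
                      (fac * matrix(1, nrow(xh), ncol(xh)))[, lead, drop = FALSE]) %*% dts)
  ifelse(den > 0, num / den, NA_real_)
}

#' Bias-corrected MPL estimate from sampled allele counts
#'
#' Applies the closed-form MPL estimator to an observed trajectory,
#' replacing each sample variance `xhat(1 - xhat)` in the denominator by its
#' unbiased version via the factor `ns / (ns - 1)` (binomial sampling makes
#' the raw sample variance biased low by exactly that factor). When `N` is
#' supplied, a likelihood-ratio confidence interval is attached (see
#' [mpl_confint()]).
#'
#' @param obs Observed trajectory: a data frame with columns `generation`,
#'   `sample_size`, `mutant_count` (as produced by [observe()] or
#'   [read_observed_tsv()]).
#' @param mu Mutation probability per generation assumed for inference.
#' @param N Population size used for the confidence interval (optional).
#'   For a codominant diploid population of `N` individuals pass the number
#'   of gametes `2N` (see [diploid_adapter()]).
#' @param bias_correction If `FALSE`, the raw (uncorrected) denominator is
#'   used — the estimator studied without the finite-sample adjustment.
#' @param level Confidence level for the interval (default 0.95).
#'
#' @return An object of class `"mpl_fit"`: a list with elements `s_hat`,
#'   `numerator`, `denominator`, `s_raw` (argmax of the observed-frequency
#'   likelihood), `ci_low`/`ci_high` (if `N` given), `bias_corrected`,
#'   `mu`, `N`, `level`, `n_timepoints` and the input `obs`. Use
#'   [generics::tidy()] / [generics::glance()] for tabular summaries.
#' @export
#' @examples
#' traj <- sim_trajectory(s = 0.02, model = "det_exact", generations = 450)
#' obs <- observe(traj, dt = 10, ns = 20, seed = 1)
#' fit <- estimate_s(obs, mu = 1e-3, N = 1000)
#' fit
estimate_s <- function(obs, mu = 0, N = NULL, bias_correction = TRUE,
                       level = 0.95) {
  obs <- validate_observed(obs)
  if (any(obs$sample_size < 2)) {
    rlang::abort("every sample size must be >= 2 for the bias correction.")
  }
  times <- obs$generation
  xh <- obs$mutant_count / obs$sample_size
  k <- length(xh) - 1
  dts <- diff(times)
  vh <- xh * (1 - xh)
  fac <- if (bias_correction) {
    obs$sample_size / (obs$sample_size - 1)
  } else {
    rep(1, k + 1)
  }
  lead <- seq_len(k)
  den <- sum(fac[lead] * dts * vh[lead])
  if (den <= 0) {
    rlang::abort(paste0("uninformative observation: all retained observed ",
                        "frequencies are 0 or 1."))
  }
  num <- xh[k + 1] - xh[1] - mu * sum(dts * (1 - 2 * xh[lead]))
  ci <- c(NA_real_, NA_real_)
  vraw <- sum(dts * vh[lead])
  s_raw <- if (vraw > 0) num / vraw else NA_real_
  if (!is.null(N)) {
    ci_tbl <- mpl_confint(xh, times, N = N, mu = mu, level = level)
    ci <- c(ci_tbl$ci_low, ci_tbl$ci_high)
    s_raw <- ci_tbl$s_raw
  }
  structure(
    list(s_hat = num / den, numerator = num, denominator = den,
         s_raw = s_raw, ci_low = ci[1], ci_high = ci[2],
         bias_corrected = bias_correction, mu = mu,
         N = if (is.null(N)) NA_real_ else N, level = level,
         n_timepoints = k + 1, obs = obs),
    class = "mpl_fit"
  )
}

#' @export
print.mpl_fit <- function(x, ...) {
  cat("MPL selection-coefficient estimate\n")
  cat(sprintf("  s_hat       : % .6f%s\n", x$s_hat,
              if (x$bias_corrected) " (bias-corrected)" else " (uncorrected)"))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %.0f%% CI      : (% .6f, % .6f)   [likelihood ratio, N = %g]\n",
                100 * x$level, x$ci_low, x$ci_high, x$N))
  }
  cat(sprintf("  numerator D : % .6f\n", x$numerator))
  cat(sprintf("  denominator V: %.6f\n", x$denominator))
  cat(sprintf("  time points : %d (generations %d-%d), mu = %g\n",
              x$n_timepoints, min(x$obs$generation), max(x$obs$generation),
              x$mu))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mpl_fit <- function(x, ...) {
  tibble::tibble(term = "s",
                 estimate = x$s_hat,
                 conf.low = x$ci_low,
                 conf.high = x$ci_high)
}

#' @export
glance.mpl_fit <- function(x, ...) {
  tibble::tibble(s_hat = x$s_hat, s_raw = x$s_raw,
                 numerator = x$numerator, denominator = x$denominator,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 bias_corrected = x$bias_corrected,
                 n_timepoints = x$n_timepoints, mu = x$mu, N = x$N)
}

# Gaussian path log-likelihood pieces for one frequency series. Transitions
# leaving a boundary frequency (v = 0) carry no information about s under
# the Gaussian density and are dropped with a warning; an error is raised
# only when every transition is dropped.
loglik_terms <- function(freqs, times, mu) {
  k <- length(freqs) - 1
  stopifnot(k >= 1)
  dts <- diff(times)
  v <- freqs * (1 - freqs)
  lead <- seq_len(k)
  keep <- v[lead] > 0
  if (!any(keep)) {
    rlang::abort("all transitions start at a monomorphic frequency; the path likelihood is degenerate.")
  }
  if (!all(keep)) {
    rlang::warn(paste0("dropping transition(s) from monomorphic generation(s) ",
                       paste(times[lead][!keep], collapse = ", ")))
  }
  list(dx = diff(freqs)[keep], dt = dts[keep], v = v[lead][keep],
       drift0 = mu * (1 - 2 * freqs[lead][keep]))
}

#' Gaussian path log-likelihood of a frequency trajectory
#'
#' The log of the product of Gaussian transition densities approximating the
#' Wright-Fisher path probability,
#' \deqn{\ell(s) = \sum_k \log \phi(x(t_{k+1}) \mid x(t_k)),}
#' where each transition is Normal with mean
#' `x + dt (s v + mu (1 - 2x))` and variance `dt v / N`. The frequency
#' quantisation constant is omitted (it does not depend on `s`, so neither
#' the argmax nor likelihood ratios are affected). `ell(s)` is exactly
#' quadratic in `s` with curvature `-N * sum(dt v)`.
#'
#' @param s Selection coefficient(s); vectorised.
#' @param freqs Frequencies at the sampling times (population or observed).
#' @param times Sampling generations.
#' @param N Population size.
#' @param mu Mutation probability per generation.
#'
#' @return Log-likelihood value(s), one per element of `s`.
#' @export
mpl_loglik <- function(s, freqs, times, N, mu = 0) {
  tr <- loglik_terms(freqs, times, mu)
  const <- sum(0.5 * log(N / (2 * pi * tr$dt * tr$v)))
  vapply(s, function(si) {
    resid <- tr$dx - tr$dt * (si * tr$v + tr$drift0)
    const - (N / 2) * sum(resid^2 / (tr$dt * tr$v))
  }, numeric(1))
}

#' Likelihood-ratio confidence interval for the selection coefficient
#'
#' The interval of values `s0` whose likelihood-ratio statistic
#' `-2 [ell(s0) - ell(s_raw)]` stays below the chi-square(1) quantile at
#' `level`. Because the Gaussian path log-likelihood is exactly quadratic in
#' `s`, the interval is available in closed form:
#' `s_raw +/- sqrt(qchisq(level, 1) / (N * V_raw))`, where `s_raw` is the
#' likelihood argmax on the supplied frequencies and `V_raw` the raw
#' (uncorrected) integrated variance of the retained transitions. Observed
#' frequencies are substituted for population frequencies when applied to
#' sampled data, so the interval reflects drift uncertainty only.
#'
#' @inheritParams mpl_loglik
#' @param level Confidence level.
#'
#' @return A one-row tibble with `s_raw`, `ci_low`, `ci_high`, `level`.
#' @export
mpl_confint <- function(freqs, times, N, mu = 0, level = 0.95) {
  tr <- loglik_terms(freqs, times, mu)
  vraw <- sum(tr$dt * tr$v)
  s_raw <- sum(tr$dx - tr$dt * tr$drift0) / vraw
  half <- sqrt(stats::qchisq(level, df = 1) / (N * vraw))
  tibble::tibble(s_raw = s_raw, ci_low = s_raw - half,
                 ci_high = s_raw + half, level = level)
}
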