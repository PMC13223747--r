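# Summarise a vector of replicate estimates into the standard one-row
# Monte-Carlo summary. The standard error of the variance uses the
# fourth-central-moment formula, so "within 3 SE" statements about
# variances are well-defined.
mc_summarise <- function(est, n_reps) {
  used <- est[!is.na(est)]
  n <- length(used)
  m <- mean(used)
  v <- stats::var(used)
  m4 <- mean((used - m)^4)
  tibble::tibble(
    n_reps = n_reps,
    n_failed = n_reps - n,
    mean = m,
    variance = v,
    se_mean = sqrt(v / n),
    se_var = sqrt((m4 - (n - 3) / (n - 1) * v^2) / n)
  )
}

#' Monte-Carlo estimator moments under sampling noise only
#'
#' Repeatedly observes a *fixed* population trajectory (the deterministic
#' model, or the mean of a Wright-Fisher ensemble) under binomial sampling
#' and summarises the resulting estimates. This isolates the sampling-only
#' component of the estimator variance; replicates whose observed
#' integrated variance is zero are excluded and counted in `n_failed`.
#'
#' @param s,mu,x0 Evolutionary parameters of the underlying trajectory.
#' @param generations Trajectory length `T` in generations.
#' @param dt Constant sampling step.
#' @param ns Fixed sample size per time point, or `NULL` to use `ns_mean`.
#' @param ns_mean Poisson mean for time-varying sample sizes (values below
#'   2 redrawn).
#' @param n_reps Number of replicate observations.
#' @param seed Integer seed governing all replicates.
#' @param mean_model `"det_exact"` to use the deterministic trajectory as
#'   the mean (the default; the WF ensemble mean closely tracks it), or
#'   `"wf_mean"` to average `wf_mean_reps` Wright-Fisher replicates.
#' @param N Population size (needed for `mean_model = "wf_mean"`).
#' @param wf_mean_reps Ensemble size for the WF mean trajectory.
#' @param keep_estimates If `TRUE`, the per-replicate estimates are
#'   attached as attribute `"estimates"`.
#'
#' @return A one-row tibble: `n_reps`, `n_failed`, `mean`, `variance`,
#'   `se_mean`, `se_var`.
#' @export
#' @examples
#' mc_sampling_only(generations = 150, ns = 20, n_reps = 500, seed = 1)
mc_sampling_only <- function(s = 0.02, mu = 1e-3, x0 = 0.1,
                             generations = 450, dt = 10, ns = 20,
                             ns_mean = NULL, n_reps = 10000, seed = NULL,
                             mean_model = c("det_exact", "wf_mean"),
                             N = 1000, wf_mean_reps = 1000,
                             keep_estimates = FALSE) {
  mean_model <- match.arg(mean_model)
  times <- seq(0, generations, by = dt)
  with_seed(seed, {
    if (mean_model == "det_exact") {
      traj <- sim_trajectory(s = s, mu = mu, x0 = x0,
                             generations = generations,
                             model = "det_exact")
      xk <- traj$frequency[match(times, traj$generation)]
    } else {
      ens <- sim_wf_ensemble(N = N, s = s, mu = mu, x0 = x0,
                             generations = generations,
                             n_reps = wf_mean_reps, keep_at = times)
      xk <- colMeans(ens)
    }
    xm <- matrix(xk, n_reps, length(times), byrow = TRUE)
    if (!is.null(ns_mean)) {
      sizes <- matrix(draw_sample_sizes(n_reps * length(times), ns_mean),
                      n_reps, length(times))
    } else {
      sizes <- rep_len(ns, length(times))
    }
    counts <- observe_counts_matrix(xm, sizes)
    szm <- if (is.matrix(sizes)) sizes else
      matrix(sizes, n_reps, length(times), byrow = TRUE)
    est <- shat_matrix(counts / szm, szm, times, mu = mu)
  })
  out <- mc_summarise(est, n_reps)
  if (keep_estimates) attr(out, "estimates") <- est
  out
}

#' Monte-Carlo estimator moments under genetic drift only
#'
#' Applies the population-frequency estimator [s_mpl()] to Wright-Fisher
#' replicate trajectories read perfectly (no sampling noise) at the design
#' times. The variance of these estimates is the drift-only component,
#' bounded below by [crlb_drift()].
#'
#' @inheritParams mc_sampling_only
#' @param N Population size.
#'
#' @return A one-row tibble as in [mc_sampling_only()].
#' @export
mc_drift_only <- function(N = 1000, s = 0.02, mu = 1e-3, x0 = 0.1,
                          generations = 450, dt = 10, n_reps = 10000,
                          seed = NULL, keep_estimates = FALSE) {
  times <- seq(0, generations, by = dt)
  ens <- sim_wf_ensemble(N = N, s = s, mu = mu, x0 = x0,
                         generations = generations, n_reps = n_reps,
                         keep_at = times, seed = seed)
  est <- smpl_matrix(ens, times, mu)
  out <- mc_summarise(est, n_reps)
  if (keep_estimates) attr(out, "estimates") <- est
  out
}

# Population-frequency estimator applied to each row of a frequency matrix;
# NA where the integrated variance vanishes.
smpl_matrix <- function(freqs, times, mu = 0) {
  k <- ncol(freqs) - 1
  dts <- diff(times)
  lead <- seq_len(k)
  v <- freqs * (1 - freqs)
  den <- as.vector(v[, lead, drop = FALSE] %*% dts)
  num <- freqs[, k + 1] - freqs[, 1] -
    mu * as.vector((1 - 2 * freqs[, lead, drop = FALSE]) %*% dts)
  ifelse(den > 0, num / den, NA_real_)
}

#' Monte-Carlo estimator moments under joint sampling and drift noise
#'
#' The full generative pipeline: Wright-Fisher replicate trajectories, each
#' observed once under binomial sampling, each yielding one bias-corrected
#' estimate. Replicates with zero observed integrated variance are excluded
#' and counted in `n_failed`.
#'
#' @inheritParams mc_sampling_only
#' @param N Population size.
#'
#' @return A one-row tibble as in [mc_sampling_only()].
#' @export
#' @examples
#' mc_joint(N = 1000, generations = 150, ns = 20, n_reps = 300, seed = 1)
mc_joint <- function(N = 1000, s = 0.02, mu = 1e-3, x0 = 0.1,
                     generations = 450, dt = 10, ns = 20, ns_mean = NULL,
                     n_reps = 10000, seed = NULL, keep_estimates = FALSE) {
  times <- seq(0, generations, by = dt)
  with_seed(seed, {
    ens <- sim_wf_ensemble(N = N, s = s, mu = mu, x0 = x0,
                           generations = generations, n_reps = n_reps,
                           keep_at = times)
    if (!is.null(ns_mean)) {
      sizes <- matrix(draw_sample_sizes(n_reps * length(times), ns_mean),
                      n_reps, length(times))
    } else {
      sizes <- matrix(ns, n_reps, length(times))
    }
    counts <- observe_counts_matrix(ens, sizes)
    est <- shat_matrix(counts / sizes, sizes, times, mu = mu)
  })
  out <- mc_summarise(est, n_reps)
  if (keep_estimates) attr(out, "estimates") <- est
  out
}
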