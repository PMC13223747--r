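#' Plot a trajectory with optional observations
#'
#' Draws the population mutant-allele frequency over generations and, if
#' supplied, overlays the observed (sampled) frequencies as points.
#'
#' @param traj Trajectory tibble (`generation`, `frequency`).
#' @param obs Optional observed trajectory from [observe()].
#'
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, obs = NULL) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$generation, .data$frequency)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "generation", y = "mutant allele frequency") +
    ggplot2::theme_minimal()
  if (!is.null(obs)) {
    obs <- validate_observed(obs)
    p <- p + ggplot2::geom_point(data = obs, colour = "firebrick", size = 1.6)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Likelihood-ratio profile of an MPL fit
#'
#' Plots `-2 [ell(s) - ell(s_raw)]` over a range of selection coefficients,
#' with the chi-square(1) cutoff and the confidence bounds marked. Needs a
#' fit computed with `N` supplied.
#'
#' @param object An `"mpl_fit"` from [estimate_s()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.mpl_fit <- function(object, ...) {
  if (is.na(object$ci_low)) {
    rlang::abort("fit has no confidence interval; refit with `N` supplied.")
  }
  obs <- object$obs
  xh <- obs$mutant_count / obs$sample_size
  width <- object$ci_high - object$ci_low
  svals <- seq(object$ci_low - width, object$ci_high + width,
               length.out = 201)
  ll <- mpl_loglik(svals, xh, obs$generation, N = object$N, mu = object$mu)
  lr <- -2 * (ll - max(ll))
  cut <- stats::qchisq(object$level, df = 1)
  df <- tibble::tibble(s = svals, lr = lr)
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$lr)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cut, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        colour = "firebrick", linetype = 3) +
    ggplot2::labs(x = "selection coefficient s",
                  y = "likelihood-ratio statistic") +
    ggplot2::theme_minimal()
}

#' Profile of the HMM objective
#'
#' @param object An `"hmm_fit"` from [fit_s_ls()]; requires the original
#'   observations via the `obs` argument.
#' @param obs The observed trajectory the fit was computed from.
#' @param span Half-width of the profiled interval around the estimate.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.hmm_fit <- function(object, obs, span = 0.02, ...) {
  svals <- seq(object$s_ls - span, object$s_ls + span, length.out = 81)
  ll <- vapply(svals, hmm_loglik, numeric(1), obs = obs, N = object$N,
               mu = object$mu, D = object$D, init_prior = object$init_prior)
  ggplot2::ggplot(tibble::tibble(s = svals, loglik = ll),
                  ggplot2::aes(.data$s, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$s_ls, colour = "firebrick",
                        linetype = 3) +
    ggplot2::labs(x = "selection coefficient s", y = "HMM log-likelihood") +
    ggplot2::theme_minimal()
}

#' Variance decomposition across trajectory lengths
#'
#' Compares Monte-Carlo joint-noise variances (e.g. from
#' [run_experiment()]) with the analytic sampling + drift decomposition.
#'
#' @param results Tibble with columns `T` and `variance` (one row per
#'   trajectory length).
#' @param s,mu,x0,dt,ns,N Evolutionary and sampling parameters used to
#'   evaluate the analytic curves.
#'
#' @return A ggplot object.
#' @export
plot_variance_decomposition <- function(results, s = 0.02, mu = 1e-3,
                                        x0 = 0.1, dt = 10, ns = 20,
                                        N = 1000) {
  theo <- purrr::map_dfr(results$T, function(T) {
    traj <- sim_trajectory(s = s, mu = mu, x0 = x0, generations = T,
                           model = "det_exact")
    theory_report(traj, dt = dt, ns = ns, N = N, mu = mu) |>
      dplyr::mutate(T = T)
  })
  ggplot2::ggplot(results, ggplot2::aes(.data$T, .data$variance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = theo,
                       ggplot2::aes(.data$T, .data$var_total),
                       colour = "firebrick") +
    ggplot2::geom_line(data = theo,
                       ggplot2::aes(.data$T, .data$crlb_drift),
                       colour = "steelblue", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "trajectory length T (generations)",
                  y = "estimator variance",
                  caption = "points: Monte Carlo; red: sampling + drift theory; blue: drift CRLB") +
    ggplot2::theme_minimal()
}
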