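test_that("sampling-noise moment formulas are exact (exhaustive enumeration)", {
  withr::with_seed(17, {
    for (ns in c(2, 4, 6)) {
      for (kk in 1:3) {
        for (mu in c(0, 1e-3)) {
          freqs <- runif(kk + 1, 0.05, 0.95)
          dt <- 10
          oracle <- enumerate_DV_moments(freqs, dt, ns, mu)
          expect_equal(var_D(freqs, dt, ns, mu), oracle$var_D,
                       tolerance = 1e-12)
          expect_equal(cov_DV(freqs, dt, ns, mu), oracle$cov_DV,
                       tolerance = 1e-12)
          expect_equal(var_V(freqs, dt, ns), oracle$var_V,
                       tolerance = 1e-12)
          # numerator and denominator are unbiased for their targets
          k <- kk
          v <- freqs * (1 - freqs)
          expect_equal(oracle$mean_V, integrated_variance(freqs, dt),
                       tolerance = 1e-12)
          expect_equal(oracle$mean_D,
                       freqs[k + 1] - freqs[1] -
                         mu * dt * sum(1 - 2 * freqs[1:k]),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("moment formulas reduce correctly in special cases", {
  x <- c(0.1, 0.25, 0.4)
  # mu = 0: Var[D] = (v(tK) + v(t0)) / ns
  expect_equal(var_D(x, 10, 20, mu = 0),
               (0.4 * 0.6 + 0.1 * 0.9) / 20)
  # both endpoints monomorphic, no mutation: no numerator noise
  expect_equal(var_D(c(0, 0.5, 0), 10, 20, mu = 0), 0)
  # Cov: zero when x(t0) = 1/2 and mu = 0; hand value at x(t0) = 0.1
  expect_equal(cov_DV(c(0.5, 0.3, 0.6), 10, 20, mu = 0), 0)
  expect_equal(cov_DV(c(0.1, 0.3, 0.6), 5, 8, mu = 0),
               -5 / 8 * 0.09 * 0.8)
  # all variances vanish on a monomorphic path
  expect_equal(var_V(c(0, 0, 1), 10, 20), 0)
  # single time point, ns = 2, x = 0.5: exact variance of the corrected
  # sample variance over the 3 outcomes {0, 1/2, 1}
  w <- 2 * c(0, 0.25, 0) # corrected sample variances
  pr <- c(0.25, 0.5, 0.25)
  expect_equal(var_V(c(0.5, 0.9), 1, 2),
               sum(pr * w^2) - sum(pr * w)^2)
})

test_that("variance scalings and the CRLB behave as dimensional analysis says", {
  traj <- sim_trajectory(model = "det_exact", generations = 450)
  x450 <- traj$frequency[seq(1, 451, 10)]
  x <- x450[x450 > 0.01 & x450 < 0.99]
  # doubling ns halves the sampling variance to first order
  r <- var_s_sampling(x, 10, 20, 1e-3) / var_s_sampling(x, 10, 40, 1e-3)
  expect_equal(r, 2, tolerance = 0.06)
  # CRLB arithmetic and N scaling
  expect_equal(crlb_drift(1000, 10), 1e-4)
  expect_equal(crlb_drift(2000, 10), 0.5e-4)
  # limits of the decomposition
  bigv <- integrated_variance(x, 10)
  expect_equal(var_total(x, 10, ns = 1e9, N = 1000, mu = 1e-3),
               crlb_drift(1000, bigv), tolerance = 1e-6)
  expect_equal(var_total(x, 10, ns = 20, N = 1e12, mu = 1e-3),
               var_s_sampling(x, 10, 20, 1e-3), tolerance = 1e-6)
})

test_that("theory report assembles consistent components", {
  traj <- sim_trajectory(model = "det_exact", generations = 450)
  rep <- theory_report(traj, dt = 10, ns = 20, N = 1000, mu = 1e-3)
  expect_equal(rep$var_total, rep$var_s_sampling + rep$crlb_drift)
  expect_true(all(c(rep$var_D, rep$var_V, rep$var_s_sampling) >= 0))
  expect_gt(rep$var_total, rep$crlb_drift)
  expect_equal(rep$mean_s,
               analytic_mean(traj$frequency[seq(1, 451, 10)], 10, 1e-3))
  coarse <- traj[seq(1, 451, 10), ]
  expect_error(theory_report(coarse, dt = 7, ns = 20, N = 1000), "multiple")
})

test_that("analytic variance tracks the sampling-only Monte Carlo", {
  mc <- mc_sampling_only(n_reps = 1e4, seed = 101)
  traj <- sim_trajectory(model = "det_exact", generations = 450)
  x <- traj$frequency[seq(1, 451, 10)]
  # first-order theory is accurate to a few percent here; the Monte-Carlo
  # SE at this replicate count dominates that error
  expect_lt(abs(mc$variance - var_s_sampling(x, 10, 20, 1e-3)),
            3 * mc$se_var)
  # mean is effectively unbiased: within 5% of the generating coefficient
  expect_lt(abs(mc$mean - 0.02), 0.05 * 0.02)
  # with the second-order ratio correction added, the analytic mean agrees
  # with the Monte Carlo to within its standard error
  smpl <- analytic_mean(x, 10, 1e-3)
  bigv <- integrated_variance(x, 10)
  corr2 <- (smpl * var_V(x, 10, 20) - cov_DV(x, 10, 20, 1e-3)) / bigv^2
  expect_lt(abs(mc$mean - (smpl + corr2)), 3 * mc$se_mean)
})

test_that("WF-ensemble mean trajectory reproduces the deterministic theory", {
  mc <- mc_sampling_only(n_reps = 2000, seed = 7, mean_model = "wf_mean",
                         N = 1000, wf_mean_reps = 1000)
  det <- mc_sampling_only(n_reps = 2000, seed = 7)
  # the WF ensemble mean lags the deterministic trajectory slightly (drift
  # curvature); the two estimator means agree to well within 10% of s
  expect_lt(abs(mc$mean - det$mean), 0.1 * 0.02)
})

test_that("drift-only variance respects and approaches the CRLB", {
  mc <- mc_drift_only(N = 1000, generations = 450, n_reps = 5000, seed = 11)
  traj <- sim_trajectory(model = "det_exact", generations = 450)
  bound <- crlb_drift(1000, integrated_variance(traj$frequency[seq(1, 451, 10)], 10))
  expect_gt(mc$variance, (1 - 3 * mc$se_var / mc$variance) * bound)
  expect_lt(mc$variance, 1.4 * bound)
  # variance decreases with trajectory length (more integrated variance)
  mc_short <- mc_drift_only(N = 1000, generations = 150, n_reps = 5000,
                            seed = 11)
  expect_gt(mc_short$variance - 3 * mc_short$se_var,
            mc$variance - 3 * mc$se_var)
})

test_that("Gaussian approximation and KL estimator are calibrated", {
  traj <- sim_trajectory(model = "det_exact", generations = 450)
  x <- traj$frequency[seq(1, 451, 10)]
  ga <- gaussian_approx(x, 10, 20, 1e-3)
  expect_equal(ga$mean, analytic_mean(x, 10, 1e-3))
  expect_equal(ga$variance, var_s_sampling(x, 10, 20, 1e-3))

  withr::with_seed(23, {
    # standard normal sample: divergence near zero
    expect_lt(kl_to_standard_normal(rnorm(1e5)), 0.01)
    # standardisation removes location/scale: N(1, 1) also near zero
    expect_lt(kl_to_standard_normal(rnorm(1e5, mean = 1)), 0.01)
    # exponential sample: strictly positive, near the numeric oracle
    kl_exp <- kl_to_standard_normal(rexp(1e5))
    expect_gt(kl_exp, 0.2)
    expect_lt(abs(kl_exp - kl_exponential_oracle()), 0.08)
  })
})

test_that("estimator distribution is closer to Gaussian at ns=50 than ns=10", {
  # the two endpoints of the sample-size range are distinguishable well
  # beyond the KL estimator's own seed-to-seed spread (~1e-4 at 1e5 reps)
  kl <- vapply(c(10, 50), function(n) {
    mc <- mc_sampling_only(ns = n, n_reps = 1e5, seed = 1000 + n,
                           keep_estimates = TRUE)
    kl_to_standard_normal(attr(mc, "estimates"))
  }, numeric(1))
  expect_gt(kl[1], kl[2] + 2e-4)

  # and at ns=50 the fitted Gaussian approximation is close in KS distance
  mc50 <- mc_sampling_only(ns = 50, n_reps = 1e5, seed = 1050,
                           keep_estimates = TRUE)
  traj <- sim_trajectory(model = "det_exact", generations = 450)
  x <- traj$frequency[seq(1, 451, 10)]
  ga <- gaussian_approx(x, 10, 50, 1e-3)
  ks <- suppressWarnings(stats::ks.test(
    attr(mc50, "estimates"), "pnorm", ga$mean, sqrt(ga$variance))$statistic)
  expect_lt(unname(ks), 0.02)
})

test_that("detection limit shrinks with more information", {
  base <- min_detectable_s(N = 1000, ns = 20, dt = 10, T = 150)
  expect_lt(min_detectable_s(N = 4000, ns = 20, dt = 10, T = 150), base)
  expect_lt(min_detectable_s(N = 1000, ns = 80, dt = 10, T = 150), base)
  expect_lt(min_detectable_s(N = 1000, ns = 20, dt = 10, T = 450), base)
  expect_error(min_detectable_s(N = 1e12, ns = 1e9, dt = 10, T = 450,
                                lower = 0.5, upper = 0.9),
               "no detection threshold")
})
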