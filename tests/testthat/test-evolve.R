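test_that("success probability matches the selection-mutation recursion", {
  # absorbing boundaries without mutation
  expect_equal(wf_success_prob(0, s = 0.02, mu = 0), 0)
  expect_equal(wf_success_prob(1, s = 0.02, mu = 0), 1)
  # frozen value, cross-checked by an independent algebraic arrangement:
  # p = (mu (1-x) + (1+s)(1-mu) x) / (1 + s x)
  x <- 0.1; s <- 0.02; mu <- 1e-3
  alt <- (mu * (1 - x) + (1 + s) * (1 - mu) * x) / (1 + s * x)
  expect_equal(wf_success_prob(x, s, mu), alt, tolerance = 1e-15)
  expect_equal(wf_success_prob(x, s, mu), 0.1025928144, tolerance = 1e-9)
  # boundaries with mutation feed back in
  expect_equal(wf_success_prob(0, s = 0.1, mu = 1e-3), 1e-3)
  expect_error(wf_success_prob(1.2, 0.02), "frequency")
})

test_that("deterministic updates agree with hand arithmetic and each other", {
  expect_equal(det_step(0.5, s = 0, mu = 0, variant = "exact"), 0.5)
  expect_equal(det_step(0.5, s = 0, mu = 0, variant = "linear"), 0.5)
  expect_equal(det_step(0.1, s = 0.02, mu = 1e-3, variant = "linear"), 0.1026)
  # exact and linear variants differ only at second order in (s, mu)
  for (sc in c(1, 0.1, 0.01)) {
    s <- 0.02 * sc; mu <- 1e-3 * sc
    gap <- abs(det_step(0.1, s, mu, "exact") - det_step(0.1, s, mu, "linear"))
    expect_lt(gap, 5 * (s^2 + mu^2 + s * mu))
  }
  expect_warning(det_step(0.999, s = 3, mu = 0, variant = "linear"),
                 "clipping")
})

test_that("WF step has the correct conditional distribution", {
  # absorbing state without mutation
  withr::with_seed(1, {
    expect_true(all(wf_step(rep(0, 50), N = 100, s = 0.05, mu = 0) == 0))
  })
  # Monte-Carlo mean within 4 standard errors of the success probability
  p <- wf_success_prob(0.1, 0.02, 1e-3)
  withr::with_seed(2, {
    draws <- wf_step(rep(0.1, 1e5), N = 1000, s = 0.02, mu = 1e-3)
  })
  se <- sqrt(p * (1 - p) / 1000 / 1e5)
  expect_lt(abs(mean(draws) - p), 4 * se)
  # exact pmf at N = 2: outcomes {0, 1/2, 1} with probs {1/4, 1/2, 1/4}
  withr::with_seed(3, {
    out <- wf_step(rep(0.5, 4e4), N = 2, s = 0, mu = 0)
  })
  emp <- as.vector(table(factor(out, levels = c(0, 0.5, 1)))) / 4e4
  expect_lt(max(abs(emp - c(0.25, 0.5, 0.25))), 4 * sqrt(0.25 * 0.75 / 4e4))
})

test_that("trajectory simulation honours model contracts", {
  const <- sim_trajectory(s = 0, mu = 0, x0 = 0.3, generations = 20,
                          model = "det_exact")
  expect_equal(const$frequency, rep(0.3, 21))
  expect_equal(const$generation, 0:20)

  # deterministic sigmoid rise towards the mutation-selection equilibrium
  det <- sim_trajectory(s = 0.02, mu = 1e-3, x0 = 0.1, generations = 450,
                        model = "det_exact")
  expect_true(all(diff(det$frequency) > 0))
  expect_gt(det$frequency[451], 0.9)

  # WF frequencies are multiples of 1/N and stay in [0, 1]
  wf <- sim_trajectory(N = 100, s = 0.02, mu = 1e-3, x0 = 0.1,
                       generations = 50, model = "wf", seed = 5)
  expect_equal(wf$frequency * 100, round(wf$frequency * 100))
  expect_true(all(wf$frequency >= 0 & wf$frequency <= 1))

  # reproducibility: same seed, bit-identical; deterministic ignores seed
  expect_identical(
    sim_trajectory(model = "wf", generations = 30, seed = 11)$frequency,
    sim_trajectory(model = "wf", generations = 30, seed = 11)$frequency
  )
  expect_error(sim_trajectory(model = "nope"), "arg")
})

test_that("neutral WF drift is a martingale with fixation prob ~ x0", {
  ens <- sim_wf_ensemble(N = 100, s = 0, mu = 0, x0 = 0.2,
                         generations = 600, n_reps = 2e4,
                         keep_at = c(0, 600), seed = 9)
  final <- ens[, 2]
  # martingale: E[x(T)] = x0
  expect_lt(abs(mean(final) - 0.2), 4 * sd(final) / sqrt(2e4))
  # after 6N generations nearly all replicates are absorbed;
  # fixation probability equals the initial frequency
  absorbed <- final %in% c(0, 1)
  expect_gt(mean(absorbed), 0.95)
  expect_lt(abs(mean(final == 1) - 0.2), 4 * sqrt(0.2 * 0.8 / 2e4))
})

test_that("ensemble simulator matches the scalar simulator stream-for-stream", {
  one <- sim_trajectory(N = 500, s = 0.03, mu = 1e-3, x0 = 0.1,
                        generations = 40, model = "wf", seed = 21)
  ens <- sim_wf_ensemble(N = 500, s = 0.03, mu = 1e-3, x0 = 0.1,
                         generations = 40, n_reps = 1, seed = 21)
  expect_equal(unname(ens[1, ]), one$frequency)
})

test_that("observation draws binomial counts with the stated moments", {
  traj <- tibble::tibble(generation = 0:100, frequency = rep(0.1, 101))
  obs <- observe(traj, dt = 10, ns = 20, seed = 3)
  expect_equal(obs$generation, seq(0, 100, 10))
  expect_true(all(obs$mutant_count >= 0 & obs$mutant_count <= 20))
  expect_equal(obs$frequency, obs$mutant_count / obs$sample_size)

  # zero frequency: counts are always zero
  z <- observe(tibble::tibble(generation = 0:10, frequency = 0),
               dt = 1, ns = 5, seed = 1)
  expect_true(all(z$mutant_count == 0))

  # moment oracle at x = 0.1, ns = 20 over many replicate draws
  flat <- tibble::tibble(generation = 0:1e4, frequency = 0.1)
  o <- observe(flat, dt = 1, ns = 20, seed = 8)
  expect_lt(abs(mean(o$frequency) - 0.1), 4 * sqrt(0.0045 / 1e4))
  expect_lt(abs(var(o$frequency) - 0.0045), 4 * 0.0045 * sqrt(2 / 1e4))

  # exact pmf at ns = 2, x = 0.5
  half <- observe(tibble::tibble(generation = 0:4e4, frequency = 0.5),
                  dt = 1, ns = 2, seed = 13)
  emp <- as.vector(table(factor(half$frequency, levels = c(0, 0.5, 1)))) /
    nrow(half)
  expect_lt(max(abs(emp - c(0.25, 0.5, 0.25))), 4 * sqrt(0.25 * 0.75 / 4e4))
})

test_that("observation validates design and sample sizes", {
  traj <- sim_trajectory(model = "det_exact", generations = 50)
  expect_error(observe(traj, times = c(0, 55), ns = 10), "not in trajectory")
  expect_error(observe(traj, times = c(10, 0), ns = 10), "increasing")
  expect_error(observe(traj, dt = 10), "ns")
  expect_error(observe(traj, dt = 10, ns = 1), ">= 2")
  expect_error(observe(traj, times = 10, ns = 5), "two sampling")

  # Poisson sizes are all >= 2 even at a small mean
  o <- observe(traj, dt = 5, ns_mean = 3, seed = 2)
  expect_true(all(o$sample_size >= 2))

  # full pipeline reproducibility: identical seeds, identical tibbles
  expect_identical(observe(traj, dt = 10, ns_mean = 20, seed = 4),
                   observe(traj, dt = 10, ns_mean = 20, seed = 4))
})
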