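#' Wright-Fisher offspring success probability
#'
#' Expected mutant-allele frequency after one generation of selection and
#' symmetric mutation, i.e. the success probability of the binomial
#' reproduction step of the Wright-Fisher model. The mutant allele has
#' Wrightian fitness `1 + s`; mutation flips alleles in both directions with
#' probability `mu` per generation.
#'
#' @param x Current mutant allele frequency, in `[0, 1]`. Vectorised.
#' @param s Selection coefficient (dimensionless); requires `1 + s > 0`.
#' @param mu Mutation probability per generation, `>= 0`.
#'
#' @return The next-generation expected frequency, in `[0, 1]`.
#' @export
#' @examples
#' wf_success_prob(0.1, s = 0.02, mu = 1e-3)
wf_success_prob <- function(x, s, mu = 0) {
  if (any(x < 0 | x > 1)) {
    rlang::abort("`x` must be a frequency in [0, 1].")
  }
  if (1 + s <= 0) {
    rlang::abort("`s` must satisfy 1 + s > 0 (positive Wrightian fitness).")
  }
  if (mu < 0) {
    rlang::abort("`mu` must be non-negative.")
  }
  ((1 + s) * x + mu * ((1 - x) - (1 + s) * x)) / (1 + s * x)
}

#' One generation of the deterministic (infinite-population) model
#'
#' The deterministic model is the Wright-Fisher model in the infinite
#' population-size limit: the frequency moves to its expectation with no
#' drift. Two variants are available: `"exact"` applies the full
#' selection-mutation recursion (identical to [wf_success_prob()]), while
#' `"linear"` applies its first-order expansion in `s` and `mu`,
#' `x + s x(1-x) + mu (1 - 2x)`. The linear update can leave `[0, 1]` for
#' extreme parameters; it is then clipped with a warning so that downstream
#' variance terms stay defined.
#'
#' @inheritParams wf_success_prob
#' @param variant `"exact"` or `"linear"`.
#'
#' @return Next-generation frequency in `[0, 1]`.
#' @export
#' @examples
#' det_step(0.1, s = 0.02, mu = 1e-3, variant = "linear") # 0.1026
det_step <- function(x, s, mu = 0, variant = c("exact", "linear")) {
  variant <- match.arg(variant)
  if (variant == "exact") {
    return(wf_success_prob(x, s, mu))
  }
  if (any(x < 0 | x > 1)) {
    rlang::abort("`x` must be a frequency in [0, 1].")
  }
  out <- x + s * x * (1 - x) + mu * (1 - 2 * x)
  if (any(out < 0 | out > 1)) {
    rlang::warn("linearised update left [0, 1]; clipping.")
    out <- pmin(1, pmax(0, out))
  }
  out
}

#' One generation of the stochastic Wright-Fisher model
#'
#' Draws the next mutant-allele count as `Binomial(N, p)` with `p` from
#' [wf_success_prob()], using the current RNG state.
#'
#' @inheritParams wf_success_prob
#' @param N Population size (haploid individuals), `>= 2`.
#'
#' @return Next-generation frequency, an integer multiple of `1/N`.
#' @export
wf_step <- function(x, N, s, mu = 0) {
  stopifnot(N >= 2)
  stats::rbinom(length(x), N, wf_success_prob(x, s, mu)) / N
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate a single-locus allele-frequency trajectory
#'
#' Iterates one of three evolutionary models from an initial frequency `x0`
#' for `generations` generations: the stochastic Wright-Fisher model
#' (`"wf"`), the exact deterministic model (`"det_exact"`), or its
#' linearisation (`"det_linear"`). Deterministic models ignore `seed`.
#'
#' @param N Population size; only used by the `"wf"` model.
#' @param s Selection coefficient.
#' @param mu Mutation probability per generation.
#' @param x0 Initial mutant allele frequency in `[0, 1]`. For the WF model
#'   it is rounded to the nearest multiple of `1/N`.
#' @param generations Number of generations to simulate (`>= 1`).
#' @param model One of `"wf"`, `"det_exact"`, `"det_linear"`.
#' @param seed Optional integer seed for the WF model; the caller's RNG
#'   state is restored on exit.
#'
#' @return A tibble with columns `generation` (0-based integers) and
#'   `frequency`, of `generations + 1` rows, carrying the model tag in
#'   attribute `"model"`.
#' @export
#' @examples
#' traj <- sim_trajectory(s = 0.02, x0 = 0.1, mu = 1e-3,
#'                        generations = 100, model = "det_exact")
#' tail(traj)
sim_trajectory <- function(N = 1000, s = 0.02, mu = 1e-3, x0 = 0.1,
                           generations = 450,
                           model = c("wf", "det_exact", "det_linear"),
                           seed = NULL) {
  model <- match.arg(model)
  stopifnot(generations >= 1, x0 >= 0, x0 <= 1, N >= 2, mu >= 0, 1 + s > 0)
  x <- numeric(generations + 1)
  if (model == "wf") {
    # track integer counts internally to avoid float drift
    n <- round(x0 * N)
    counts <- integer(generations + 1)
    counts[1] <- n
    with_seed(seed, {
      for (t in seq_len(generations)) {
        p <- wf_success_prob(counts[t] / N, s, mu)
        counts[t + 1] <- stats::rbinom(1, N, p)
      }
    })
    x <- counts / N
  } else {
    variant <- if (model == "det_exact") "exact" else "linear"
    x[1] <- x0
    for (t in seq_len(generations)) {
      x[t + 1] <- det_step(x[t], s, mu, variant = variant)
    }
  }
  out <- tibble::tibble(generation = 0:generations, frequency = x)
  attr(out, "model") <- model
  out
}

#' Simulate an ensemble of Wright-Fisher trajectories
#'
#' Vectorised replicate simulator used by the Monte-Carlo harness: all
#' replicates advance one generation at a time as a single binomial draw.
#' One root seed governs the whole ensemble.
#'
#' @inheritParams sim_trajectory
#' @param n_reps Number of independent replicate trajectories.
#' @param keep_at Generations at which frequencies are retained (default:
#'   every generation). Must be a subset of `0:generations`.
#'
#' @return A numeric matrix of dimension `n_reps x length(keep_at)` of
#'   mutant allele frequencies, with `keep_at` as column names.
#' @export
sim_wf_ensemble <- function(N = 1000, s = 0.02, mu = 1e-3, x0 = 0.1,
                            generations = 450, n_reps = 1000,
                            keep_at = NULL, seed = NULL) {
  stopifnot(n_reps >= 1, generations >= 1)
  if (is.null(keep_at)) keep_at <- 0:generations
  stopifnot(all(keep_at %in% 0:generations))
  keep_at <- sort(unique(as.integer(keep_at)))
  out <- matrix(NA_real_, n_reps, length(keep_at),
                dimnames = list(NULL, keep_at))
  cnt <- rep(round(x0 * N), n_reps)
  j <- 1L
  if (0L %in% keep_at) {
    out[, 1] <- cnt / N
    j <- 2L
  }
  with_seed(seed, {
    for (t in seq_len(generations)) {
      cnt <- stats::rbinom(n_reps, N, wf_success_prob(cnt / N, s, mu))
      if (j <= length(keep_at) && keep_at[j] == t) {
        out[, j] <- cnt / N
        j <- j + 1L
      }
    }
  })
  out
}

# Draw per-time-point Poisson sample sizes with mean ns_mean, redrawing any
# value < 2 (a size of 0 or 1 leaves the ns/(ns-1) correction undefined).
draw_sample_sizes <- function(k, ns_mean) {
  sizes <- stats::rpois(k, ns_mean)
  while (any(bad <- sizes < 2)) {
    sizes[bad] <- stats::rpois(sum(bad), ns_mean)
  }
  sizes
}

#' Observe a trajectory under binomial (limited) sampling
#'
#' At each retained time point `t_k`, draws a mutant count
#' `c(t_k) ~ Binomial(ns(t_k), x(t_k))` independently of other time points.
#' Sample sizes are either fixed (`ns`, scalar or one per time point) or
#' Poisson with mean `ns_mean` (values below 2 are redrawn). The binomial
#' model is used even when `ns` equals the population size, matching the
#' standard sampling model for this estimator (sampling with replacement).
#'
#' @param traj A trajectory tibble from [sim_trajectory()] (columns
#'   `generation`, `frequency`).
#' @param dt Constant sampling step: observation times `0, dt, 2*dt, ...`
#'   up to the final generation. Ignored if `times` is given.
#' @param times Explicit strictly increasing sampling generations; must be
#'   present in `traj$generation`.
#' @param ns Fixed sample size(s), each `>= 2`.
#' @param ns_mean Poisson mean for time-varying sample sizes.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#'
#' @return A tibble with columns `generation`, `sample_size`,
#'   `mutant_count` and `frequency` (the observed frequency
#'   `mutant_count / sample_size`).
#' @export
#' @examples
#' traj <- sim_trajectory(model = "det_exact", generations = 100)
#' observe(traj, dt = 10, ns = 20, seed = 1)
observe <- function(traj, dt = NULL, times = NULL, ns = NULL,
                    ns_mean = NULL, seed = NULL) {
  stopifnot(is.data.frame(traj),
            all(c("generation", "frequency") %in% names(traj)))
  if (is.null(times)) {
    if (is.null(dt)) {
      rlang::abort("supply either `dt` or `times`.")
    }
    times <- seq(min(traj$generation), max(traj$generation), by = dt)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("`times` must be strictly increasing.")
  }
  miss <- setdiff(times, traj$generation)
  if (length(miss) > 0) {
    rlang::abort(paste0("sampling generation(s) not in trajectory: ",
                        paste(utils::head(miss, 5), collapse = ", ")))
  }
  if (length(times) < 2) {
    rlang::abort("need at least two sampling time points.")
  }
  x <- traj$frequency[match(times, traj$generation)]
  with_seed(seed, {
    if (!is.null(ns_mean)) {
      sizes <- draw_sample_sizes(length(times), ns_mean)
    } else if (!is.null(ns)) {
      if (any(ns < 2)) {
        rlang::abort("every sample size must be >= 2.")
      }
      sizes <- rep_len(as.integer(ns), length(times))
    } else {
      rlang::abort("supply either `ns` or `ns_mean`.")
    }
    counts <- stats::rbinom(length(times), sizes, x)
  })
  tibble::tibble(generation = as.integer(times),
                 sample_size = as.integer(sizes),
                 mutant_count = as.integer(counts),
                 frequency = counts / sizes)
}

# Vectorised observation of a frequency matrix (replicates x time points):
# independent binomial counts per cell. `sizes` is a vector (recycled per
# row) or a matrix of matching dimension. Returns a count matrix.
observe_counts_matrix <- function(freqs, sizes) {
  if (!is.matrix(sizes)) {
    sizes <- matrix(sizes, nrow(freqs), ncol(freqs), byrow = TRUE)
  }
  matrix(stats::rbinom(length(freqs), sizes, freqs),
         nrow(freqs), ncol(freqs))
}
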