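# Validate an observed-trajectory data frame; returns it sorted with an
# observed `frequency` column added.
validate_observed <- function(obs) {
  need <- c("generation", "sample_size", "mutant_count")
  if (!is.data.frame(obs) || !all(need %in% names(obs))) {
    rlang::abort(paste0("observed trajectory needs columns ",
                        paste(need, collapse = ", "), "."))
  }
  if (nrow(obs) < 1) {
    rlang::abort("observed trajectory is empty.")
  }
  if (anyDuplicated(obs$generation)) {
    rlang::abort("duplicate generations in observed trajectory.")
  }
  obs <- dplyr::arrange(obs, .data$generation)
  bad <- which(obs$mutant_count < 0 | obs$mutant_count > obs$sample_size)
  if (length(bad) > 0) {
    rlang::abort(paste0("mutant_count outside [0, sample_size] at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  if (any(obs$generation < 0) || any(obs$generation != round(obs$generation))) {
    rlang::abort("generations must be non-negative integers.")
  }
  obs$frequency <- obs$mutant_count / obs$sample_size
  obs
}

#' Read and write allele-count time series as TSV
#'
#' Observed trajectories use the three tab-separated columns
#' `generation`, `sample_size`, `mutant_count` (header required, UTF-8,
#' generations non-negative integers sorted increasing); trajectories use
#' `generation`, `frequency`. Malformed rows are reported with their
#' numbers, and counts exceeding sample sizes are rejected.
#'
#' @param path File path.
#' @param obs,traj Tibble to write.
#'
#' @return `read_observed_tsv()` returns a validated observed-trajectory
#'   tibble (with an added observed `frequency` column);
#'   `read_trajectory_tsv()` a trajectory tibble. Writers return the input
#'   invisibly.
#' @name trajectory_io
#' @export
read_observed_tsv <- function(path) {
  # readr's own warnings are redundant here: parse problems and header
  # mismatches are re-diagnosed below with precise messages
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    generation = readr::col_integer(),
    sample_size = readr::col_integer(),
    mutant_count = readr::col_integer()
  ), progress = FALSE))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    rlang::abort(paste0("malformed TSV at line(s) ",
                        paste(utils::head(prob$row, 5), collapse = ", "), "."))
  }
  if (!identical(names(df)[1:3], c("generation", "sample_size", "mutant_count"))) {
    rlang::abort("header must be: generation, sample_size, mutant_count.")
  }
  validate_observed(tibble::as_tibble(df))
}

#' @rdname trajectory_io
#' @export
write_observed_tsv <- function(obs, path) {
  obs <- validate_observed(obs)
  readr::write_tsv(obs[c("generation", "sample_size", "mutant_count")], path)
  invisible(obs)
}

#' @rdname trajectory_io
#' @export
read_trajectory_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    generation = readr::col_integer(),
    frequency = readr::col_double()
  ), progress = FALSE)
  if (!identical(names(df)[1:2], c("generation", "frequency"))) {
    rlang::abort("header must be: generation, frequency.")
  }
  if (any(df$frequency < 0 | df$frequency > 1)) {
    rlang::abort("frequencies must lie in [0, 1].")
  }
  tibble::as_tibble(df)
}

#' @rdname trajectory_io
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(all(c("generation", "frequency") %in% names(traj)))
  readr::write_tsv(traj[c("generation", "frequency")], path)
  invisible(traj)
}

#' Codominant-diploid adapter for allele-count data
#'
#' Under codominance (genotype fitnesses 1, `1+s`, `1+2s`), diploid
#' allele-frequency dynamics reduce to the haploid model acting on the `2N`
#' gametes. The adapter therefore passes allele-count data through
#' unchanged and sets the effective population size used by the estimator
#' to `2N`. Applying it twice is guarded against via an attribute.
#'
#' @param obs Observed trajectory of *allele* counts.
#' @param twoN Number of gametes (`2N`), e.g. 1000 for 500 diploids.
#'
#' @return A list with elements `obs` (flagged) and `effective_N = twoN`.
#' @export
diploid_adapter <- function(obs, twoN) {
  obs <- validate_observed(obs)
  if (isTRUE(attr(obs, "diploid_adapted"))) {
    rlang::abort("observed trajectory has already been diploid-adapted.")
  }
  attr(obs, "diploid_adapted") <- TRUE
  list(obs = obs, effective_N = twoN)
}

#' Run a seeded Monte-Carlo experiment sweep
#'
#' Sweeps the joint-noise Monte-Carlo harness over a grid of trajectory
#' lengths, sample sizes and sampling steps, producing one summary row per
#' setting. The configuration is a named list with components `params`
#' (`N`, `s`, `mu`, `x0`), `grid` (vectors `T`, `ns`, `dt`, crossed),
#' `n_reps` and `seed`; unknown components are rejected. Reruns with the
#' same configuration are bit-identical. If `out_dir` is given, the results
#' are written to `results.tsv` alongside a plain-text log recording the
#' package version, seed and configuration hash.
#'
#' @param config Configuration list (see Details), or a path to a JSON file
#'   with the same structure.
#' @param out_dir Optional output directory.
#'
#' @return A tibble with columns `T`, `ns`, `dt` and the
#'   [mc_joint()] summary columns.
#' @export
#' @examples
#' cfg <- list(params = list(N = 200, s = 0.02, mu = 1e-3, x0 = 0.1),
#'             grid = list(T = c(50, 100), ns = 10, dt = 10),
#'             n_reps = 50, seed = 1)
#' run_experiment(cfg)
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  allowed <- c("params", "grid", "n_reps", "seed", "schema")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", "), "."))
  }
  p <- config$params
  stopifnot(all(c("N", "s", "mu", "x0") %in% names(p)),
            all(c("T", "ns", "dt") %in% names(config$grid)))
  settings <- tidyr_free_grid(config$grid)
  res <- purrr::pmap(settings, function(T, ns, dt, .row) {
    mc_joint(N = p$N, s = p$s, mu = p$mu, x0 = p$x0, generations = T,
             dt = dt, ns = ns, n_reps = config$n_reps,
             # distinct deterministic substream per setting
             seed = config$seed + 7919L * .row)
  })
  out <- dplyr::bind_cols(settings[c("T", "ns", "dt")],
                          dplyr::bind_rows(res))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "results.tsv"))
    writeLines(c(
      sprintf("mplselect %s | R %s", as.character(utils::packageVersion("mplselect")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", config$seed),
      sprintf("config hash: %s", rlang::hash(config)),
      sprintf("run at: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    ), file.path(out_dir, "experiment.log"))
  }
  out
}

# expand.grid over the sweep lists, with a row index for seed spawning
tidyr_free_grid <- function(grid) {
  g <- expand.grid(T = grid$T, ns = grid$ns, dt = grid$dt,
                   KEEP.OUT.ATTRS = FALSE)
  g$.row <- seq_len(nrow(g))
  tibble::as_tibble(g)
}
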