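#' Bootstrap specification
#'
#' Protocol for trajectory-elimination bootstrap error estimation: a number
#' of independent runs, each discarding a fixed fraction of the trajectories
#' (chosen by a seeded draw without replacement) and rebuilding the model
#' from clustering onward with the same parameters.
#'
#' @param n_runs Number of bootstrap runs (default 7, `>= 2`).
#' @param drop_fraction Fraction of trajectories eliminated per run
#'   (default 0.2, in (0, 1)).
#' @param seed Integer seed; run `r` uses `seed + r` for both the trajectory
#'   draw and the re-clustering.
#' @return A `bootstrap_spec` object.
#' @export
bootstrap_spec <- function(n_runs = 7L, drop_fraction = 0.2, seed = 0L) {
  n_runs <- check_count(n_runs, "n_runs", min = 2L)
  if (!is.numeric(drop_fraction) || length(drop_fraction) != 1L ||
      drop_fraction <= 0 || drop_fraction >= 1) {
    stop_ligandmsm("`drop_fraction` must lie strictly between 0 and 1")
  }
  structure(list(n_runs = n_runs, drop_fraction = drop_fraction,
                 seed = check_seed(seed)),
            class = "bootstrap_spec")
}

#' Bootstrap errors for pipeline observables
#'
#' Repeats the clustering -> MSM -> kinetics stages `n_runs` times, each time
#' eliminating `floor(drop_fraction * N)` trajectories chosen by a seeded
#' draw without replacement (independently across runs), and reports the
#' mean and sample standard deviation of each observable (kon, koff, dG0,
#' slowest implied timescale) next to the full-data point estimate.  Runs in
#' which the reduced data loses ergodicity (or degenerates otherwise) are
#' skipped with a warning and reported in `n_effective_runs`.
#'
#' @param features List of [feature_trajectory()] objects (the full data).
#' @param config Validated pipeline configuration ([validate_config()]).
#' @param flags Optional list of [coordination_flags()] aligned with
#'   `features`.
#' @param spec A [bootstrap_spec()].
#' @return A data frame with columns `observable`, `point`, `mean`, `sd`,
#'   `n_effective_runs`; per-run values are attached as attribute `runs`,
#'   and the retained trajectory indices as attribute `partitions`.
#' @export
bootstrap_observables <- function(features, config, flags = NULL,
                                  spec = bootstrap_spec()) {
  if (!inherits(spec, "bootstrap_spec")) {
    stop_ligandmsm("`spec` must be a bootstrap_spec")
  }
  features <- as_ftraj_list(features)
  N <- length(features)
  n_drop <- floor(spec$drop_fraction * N)
  if (N - n_drop < 2L) {
    stop_ligandmsm("too few trajectories to bootstrap at this drop fraction")
  }
  point_fit <- fit_msm_pipeline(features, config, flags = flags)
  point <- pipeline_observables(point_fit)
  runs <- matrix(NA_real_, spec$n_runs, length(point),
                 dimnames = list(NULL, names(point)))
  partitions <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    run_seed <- spec$seed + r
    keep <- withr::with_seed(run_seed, {
      sort(sample.int(N, N - n_drop))
    })
    partitions[[r]] <- keep
    fit <- try(fit_msm_pipeline(features[keep], config,
                                flags = if (!is.null(flags)) flags[keep],
                                cluster_seed = run_seed),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning(sprintf("bootstrap run %d skipped: %s", r,
                      conditionMessage(attr(fit, "condition"))))
      next
    }
    runs[r, ] <- pipeline_observables(fit)
  }
  ok <- !is.na(runs[, 1L])
  out <- data.frame(
    observable = names(point),
    point = as.numeric(point),
    mean = colMeans(runs[ok, , drop = FALSE]),
    sd = apply(runs[ok, , drop = FALSE], 2, stats::sd),
    n_effective_runs = sum(ok),
    row.names = NULL
  )
  attr(out, "runs") <- runs
  attr(out, "partitions") <- partitions
  attr(out, "point_fit") <- point_fit
  out
}
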