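#' Feature trajectory
#'
#' A per-ligand time series of feature vectors with a fixed frame spacing.
#' This is the common currency of the pipeline: contact-map featurization,
#' synthetic state embedding and TICA projection all produce (or consume)
#' feature trajectories.
#'
#' @param frames Numeric matrix, one frame per row (`T x F`, `T >= 2`,
#'   `F >= 1`), no missing values.
#' @param frame_dt Frame spacing in ns, `> 0`.
#' @param feature_names Optional character vector of length `F`.
#' @param source Optional identifier (e.g. `c(run = 1, ligand = 3)`).
#' @return A `feature_trajectory` object.
#' @export
feature_trajectory <- function(frames, frame_dt, feature_names = NULL,
                               source = NULL) {
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  if (nrow(frames) < 2L || ncol(frames) < 1L) {
    stop_ligandmsm("`frames` must have at least 2 rows and 1 column")
  }
  if (anyNA(frames) || any(!is.finite(frames))) {
    stop_ligandmsm("`frames` must not contain missing or non-finite values")
  }
  check_scalar_positive(frame_dt, "frame_dt")
  if (!is.null(feature_names)) {
    if (length(feature_names) != ncol(frames)) {
      stop_ligandmsm("`feature_names` length must equal the number of features")
    }
    colnames(frames) <- feature_names
  }
  structure(
    list(frames = frames, frame_dt = frame_dt,
         feature_names = feature_names %||% colnames(frames),
         source = source),
    class = "feature_trajectory"
  )
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf("Feature trajectory: %d frames x %d features, frame_dt = %g ns\n",
              nrow(x$frames), ncol(x$frames), x$frame_dt))
  invisible(x)
}

#' Discrete (microstate) trajectory
#'
#' @param states Integer vector of 1-based microstate indices.
#' @param frame_dt Frame spacing in ns.
#' @param n_microstates Total number of microstates the indices refer to.
#' @param source Optional identifier carried over from the feature trajectory.
#' @return A `discrete_trajectory` object.
#' @export
discrete_trajectory <- function(states, frame_dt, n_microstates,
                                source = NULL) {
  states <- as.integer(states)
  if (length(states) < 1L || anyNA(states)) {
    stop_ligandmsm("`states` must be a nonempty integer vector without NA")
  }
  n_microstates <- check_count(n_microstates, "n_microstates")
  if (any(states < 1L) || any(states > n_microstates)) {
    stop_ligandmsm("state indices must lie in [1, n_microstates]")
  }
  check_scalar_positive(frame_dt, "frame_dt")
  structure(
    list(states = states, frame_dt = frame_dt,
         n_microstates = n_microstates, source = source),
    class = "discrete_trajectory"
  )
}

#' @export
print.discrete_trajectory <- function(x, ...) {
  cat(sprintf(
    "Discrete trajectory: %d frames, %d microstates, frame_dt = %g ns\n",
    length(x$states), x$n_microstates, x$frame_dt))
  invisible(x)
}

as_dtraj_list <- function(dtrajs) {
  if (inherits(dtrajs, "discrete_trajectory")) dtrajs <- list(dtrajs)
  if (!length(dtrajs) || !all(vapply(dtrajs, inherits, TRUE, "discrete_trajectory"))) {
    stop_ligandmsm("expected a list of `discrete_trajectory` objects")
  }
  dtrajs
}

as_ftraj_list <- function(trajs) {
  if (inherits(trajs, "feature_trajectory")) trajs <- list(trajs)
  if (!length(trajs) || !all(vapply(trajs, inherits, TRUE, "feature_trajectory"))) {
    stop_ligandmsm("expected a list of `feature_trajectory` objects")
  }
  trajs
}
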