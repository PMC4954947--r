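#' Fit time-lagged independent component analysis (TICA)
#'
#' Solves the generalized eigenproblem `C(tau) v = lambda C(0) v` with
#' mean-free, symmetrized time-lagged covariances pooled over trajectories:
#' `C(tau) = 1/2 <x_t x_{t+tau}' + x_{t+tau} x_t'>`.  The leading eigenvectors
#' are the slowest linear order parameters of the data; projecting
#' high-dimensional contact maps onto them gives a space in which geometric
#' clustering produces kinetically meaningful microstates.
#'
#' Symmetrized estimation guarantees a real spectrum.  The instantaneous
#' covariance is regularized with a ridge `eps I`,
#' `eps = 1e-6 trace(C0)/F`, because binary contact features are frequently
#' collinear; all-constant feature columns are dropped (with a warning) and
#' recorded in the model so [transform_tica()] stays consistent.
#'
#' @param trajectories List of [feature_trajectory()] objects with equal
#'   feature count and frame spacing.
#' @param lag Lag time in ns; must be a positive integer multiple of the
#'   frame spacing (no interpolation is performed).
#' @param dim Number of components to keep (`<=` number of usable features).
#' @return A `tica_model` with fields `mean`, `eigenvalues` (descending),
#'   `components` (columns normalized to unit instantaneous variance),
#'   `lag`, `kept` (retained feature columns) and `regularization`.
#' @export
fit_tica <- function(trajectories, lag, dim) {
  trajectories <- as_ftraj_list(trajectories)
  check_scalar_positive(lag, "lag")
  frame_dt <- trajectories[[1]]$frame_dt
  F_ <- ncol(trajectories[[1]]$frames)
  for (tr in trajectories) {
    if (abs(tr$frame_dt - frame_dt) > 1e-12) {
      stop_ligandmsm("all trajectories must share the same frame spacing")
    }
    if (ncol(tr$frames) != F_) {
      stop_ligandmsm("all trajectories must share the same feature count")
    }
  }
  tau <- lag_in_frames(lag, frame_dt)
  usable <- vapply(trajectories, function(tr) nrow(tr$frames) > tau, TRUE)
  if (!any(usable)) {
    stop_ligandmsm("no trajectory is longer than the lag")
  }
  trajectories <- trajectories[usable]

  # pooled mean over all frames entering the pair estimate
  sums <- Reduce(`+`, lapply(trajectories, function(tr) {
    T_ <- nrow(tr$frames)
    colSums(tr$frames[seq_len(T_ - tau), , drop = FALSE]) +
      colSums(tr$frames[(tau + 1):T_, , drop = FALSE])
  }))
  n_pairs <- sum(vapply(trajectories, function(tr) nrow(tr$frames) - tau, 1))
  mu <- sums / (2 * n_pairs)

  C0 <- matrix(0, F_, F_)
  Ct <- matrix(0, F_, F_)
  for (tr in trajectories) {
    T_ <- nrow(tr$frames)
    X0 <- sweep(tr$frames[seq_len(T_ - tau), , drop = FALSE], 2, mu)
    X1 <- sweep(tr$frames[(tau + 1):T_, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(X0) + crossprod(X1)
    Ct <- Ct + crossprod(X0, X1)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- (Ct + t(Ct)) / (2 * n_pairs)

  kept <- unname(which(diag(C0) > 1e-12))
  if (length(kept) < F_) {
    warning(sprintf("dropping %d all-constant feature column(s)",
                    F_ - length(kept)))
  }
  if (length(kept) == 0L) {
    stop_ligandmsm("all feature columns are constant")
  }
  dim <- check_count(dim, "dim")
  if (dim > length(kept)) {
    stop_ligandmsm("`dim` exceeds the number of non-constant features")
  }
  C0 <- C0[kept, kept, drop = FALSE]
  Ct <- Ct[kept, kept, drop = FALSE]
  eps <- 1e-6 * sum(diag(C0)) / length(kept)
  C0r <- C0 + diag(eps, nrow(C0))

  # generalized symmetric eigenproblem via Cholesky whitening
  L <- chol(C0r)                       # C0r = L'L
  Linv <- backsolve(L, diag(nrow(L)))  # L^{-1}
  A <- t(Linv) %*% Ct %*% Linv
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  comp <- Linv %*% es$vectors[, seq_len(dim), drop = FALSE]
  structure(
    list(mean = mu, eigenvalues = es$values[seq_len(dim)],
         components = comp, lag = lag, kept = kept,
         regularization = eps, frame_dt = frame_dt),
    class = "tica_model"
  )
}

lag_in_frames <- function(lag, frame_dt) {
  tau <- lag / frame_dt
  if (abs(tau - round(tau)) > 1e-9 || round(tau) < 1) {
    stop_ligandmsm(sprintf(
      "lag (%g ns) must be a positive integer multiple of frame_dt (%g ns)",
      lag, frame_dt))
  }
  as.integer(round(tau))
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("TICA model: %d component(s), lag = %g ns\n",
              ncol(x$components), x$lag))
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Project a feature trajectory onto TICA components
#'
#' Applies the affine map `(x - mean) %*% components`; frame spacing is
#' preserved.
#'
#' @param model A `tica_model` from [fit_tica()].
#' @param trajectory A [feature_trajectory()] with the feature count the
#'   model was fitted on.
#' @return A [feature_trajectory()] with one column per component.
#' @export
transform_tica <- function(model, trajectory) {
  if (!inherits(model, "tica_model")) stop_ligandmsm("`model` must be a tica_model")
  if (!inherits(trajectory, "feature_trajectory")) {
    stop_ligandmsm("`trajectory` must be a feature_trajectory")
  }
  if (ncol(trajectory$frames) != length(model$mean)) {
    stop_ligandmsm("feature count does not match the TICA model")
  }
  X <- sweep(trajectory$frames, 2, model$mean)[, model$kept, drop = FALSE]
  feature_trajectory(X %*% model$components, frame_dt = trajectory$frame_dt,
                     feature_names = paste0("tic_", seq_len(ncol(model$components))),
                     source = trajectory$source)
}

#' Serialize / deserialize a TICA model to JSON
#'
#' @param model A `tica_model`.
#' @param path File path.
#' @return `path` (write) or a `tica_model` (read).
#' @export
write_tica_model <- function(model, path) {
  stopifnot(inherits(model, "tica_model"))
  jsonlite::write_json(
    list(mean = model$mean, eigenvalues = model$eigenvalues,
         components = model$components, lag = model$lag, kept = model$kept,
         regularization = model$regularization, frame_dt = model$frame_dt),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tica_model
#' @export
read_tica_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mean = as.numeric(x$mean), eigenvalues = as.numeric(x$eigenvalues),
         components = as.matrix(x$components), lag = x$lag,
         kept = as.integer(x$kept), regularization = x$regularization,
         frame_dt = x$frame_dt),
    class = "tica_model"
  )
}
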