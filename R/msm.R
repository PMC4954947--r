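#' Count microstate transitions at a lag time
#'
#' Sliding-window transition counts
#' `C[i, j] = #\{t : s_t = i, s_(t+tau) = j\}` summed over trajectories; no
#' pair crosses a trajectory boundary.  These are the sufficient statistics
#' for transition-matrix estimation at lag `tau`.
#'
#' @param dtrajs List of [discrete_trajectory()] objects over a common
#'   microstate space.
#' @param lag Lag time in ns, a positive integer multiple of the frame
#'   spacing.
#' @param mode Counting mode; only `"sliding"` is provided.
#' @return A `count_model` with fields `counts` (n x n), `lag`,
#'   `counting_mode` and `active_set` (the largest strongly connected
#'   component, see [largest_connected_set()]).
#' @export
count_transitions <- function(dtrajs, lag, mode = "sliding") {
  dtrajs <- as_dtraj_list(dtrajs)
  mode <- match.arg(mode, "sliding")
  frame_dt <- dtrajs[[1]]$frame_dt
  n <- max(vapply(dtrajs, function(d) d$n_microstates, 1L))
  tau <- lag_in_frames(lag, frame_dt)
  counts <- matrix(0, n, n)
  any_long <- FALSE
  for (d in dtrajs) {
    s <- d$states
    T_ <- length(s)
    if (T_ <= tau) next
    any_long <- TRUE
    i <- s[seq_len(T_ - tau)]
    j <- s[(tau + 1):T_]
    tab <- tabulate((j - 1L) * n + i, nbins = n * n)
    counts <- counts + matrix(tab, n, n)
  }
  if (!any_long) {
    stop_ligandmsm("no trajectory is longer than the lag")
  }
  structure(
    list(counts = counts, lag = lag, counting_mode = mode,
         active_set = largest_connected_set(counts), frame_dt = frame_dt),
    class = "count_model"
  )
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf(
    "Count model: %d microstates (%d active), lag = %g ns, %s counts, total %g\n",
    nrow(x$counts), length(x$active_set), x$lag, x$counting_mode,
    sum(x$counts)))
  invisible(x)
}

#' Largest strongly connected set of a count matrix
#'
#' Maximal strongly connected component of the directed graph with an edge
#' `i -> j` whenever `C[i, j] > 0`.  Size ties are broken by total counts
#' inside the component, then by lowest state index.  Estimating an ergodic
#' model requires restricting to this set.
#'
#' @param counts Nonnegative square matrix (or a `count_model`).
#' @return Sorted integer vector of state indices.
#' @export
largest_connected_set <- function(counts) {
  if (inherits(counts, "count_model")) counts <- counts$counts
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1,
                                           mode = "directed", diag = TRUE)
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    tot <- vapply(best, function(b) {
      idx <- which(comp$membership == b)
      sum(counts[idx, idx])
    }, 1)
    best <- best[tot == max(tot)]
    if (length(best) > 1L) {
      low <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
      best <- best[which.min(low)]
    }
  }
  sort(which(comp$membership == best[1L]))
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximizes the trajectory likelihood `sum C_ij log T_ij` over row-stochastic
#' matrices satisfying detailed balance `pi_i T_ij = pi_j T_ji`, restricted to
#' the active (strongly connected) set.  Uses the standard self-consistent
#' fixed-point iteration on the symmetric auxiliary variables
#' `x_ij = x_ji` with `T_ij = x_ij / sum_k x_ik`:
#' `x_ij <- (C_ij + C_ji) / (C_i/x_i + C_j/x_j)`.
#'
#' @param counts A `count_model` from [count_transitions()].
#' @param tol Convergence threshold on the maximum relative change of `x`
#'   between sweeps.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return A `transition_model` with fields `T` (row-stochastic, detailed
#'   balance holds to numerical precision), `pi` (stationary distribution),
#'   `lag`, `active_set` (original microstate indices) and `loglik`.
#' @export
estimate_reversible <- function(counts, tol = 1e-12, max_iter = 1e6) {
  if (!inherits(counts, "count_model")) {
    stop_ligandmsm("`counts` must be a count_model")
  }
  act <- counts$active_set
  if (length(act) < 1L) stop_ligandmsm("empty active set")
  C <- counts$counts[act, act, drop = FALSE]
  n <- nrow(C)
  if (n == 1L) {
    T_ <- matrix(1, 1, 1)
    return(structure(
      list(T = T_, pi = 1, lag = counts$lag, active_set = act,
           loglik = 0, frame_dt = counts$frame_dt),
      class = "transition_model"))
  }
  Csym <- C + t(C)
  Ci <- rowSums(C)
  x <- Csym / sum(Csym)
  xi <- rowSums(x)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- outer(Ci / xi, Ci / xi, `+`)
    x_new <- Csym / denom
    x_new[Csym == 0] <- 0
    x_new <- x_new / sum(x_new)
    delta <- max(abs(x_new - x) / pmax(x, 1e-300))
    x <- x_new
    xi <- rowSums(x)
    if (delta < tol) break
    if (iter >= max_iter) {
      stop_ligandmsm(sprintf(
        "reversible MLE did not converge (residual %.3g after %d sweeps)",
        delta, iter))
    }
  }
  T_ <- x / xi
  pi <- xi / sum(xi)
  loglik <- sum(C[C > 0] * log(T_[C > 0]))
  structure(
    list(T = T_, pi = pi, lag = counts$lag, active_set = act,
         loglik = loglik, frame_dt = counts$frame_dt),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "Reversible transition model: %d active microstates, lag = %g ns, loglik = %.6g\n",
    nrow(x$T), x$lag, x$loglik))
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' The left eigenvector of `T` with eigenvalue 1, normalized to a strictly
#' positive probability vector.  Requires `T` irreducible.
#'
#' @param T_ Row-stochastic matrix or a `transition_model`.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(T_) {
  if (inherits(T_, "transition_model")) return(T_$pi)
  T_ <- as.matrix(T_)
  if (!is_irreducible(T_ - diag(diag(T_)))) {
    stop_ligandmsm("`T` is reducible; the stationary distribution is not unique")
  }
  n <- nrow(T_)
  A <- t(T_) - diag(n)
  A[n, ] <- 1
  pi <- solve(A, c(rep(0, n - 1L), 1))
  pi <- as.numeric(pi)
  if (any(pi <= 0)) stop_ligandmsm("stationary solve produced non-positive entries")
  pi / sum(pi)
}

# real spectrum of a reversible T via the pi-symmetrized similar matrix
reversible_eigen <- function(T_, pi) {
  s <- sqrt(pi)
  S <- (s %o% (1 / s)) * T_
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(values = es$values,
       # right eigenvectors of T
       vectors = es$vectors / s)
}

#' Implied relaxation timescales
#'
#' Converts transition-matrix eigenvalues to relaxation timescales
#' `tau_s = -lag / log(lambda_s)` for eigenvalues in (0, 1).  The unit
#' eigenvalue is the stationary process; eigenvalues within `1e-12` of 1 are
#' reported as `Inf`, and non-positive eigenvalues as `NA` (no timescale is
#' defined for them).
#'
#' @param model A `transition_model` (or a row-stochastic matrix plus `lag`).
#' @param lag Lag time in ns (taken from the model when available).
#' @param n_timescales Optional cap on the number of reported timescales
#'   (excluding the stationary eigenvalue).
#' @return A `spectral_result` with `eigenvalues` (descending) and
#'   `timescales` (ns, aligned with `eigenvalues[-1]`).
#' @export
implied_timescales <- function(model, lag = NULL, n_timescales = NULL) {
  if (inherits(model, "transition_model")) {
    T_ <- model$T
    pi <- model$pi
    lag <- lag %||% model$lag
  } else {
    T_ <- as.matrix(model)
    pi <- stationary_distribution(T_)
  }
  if (is.null(lag)) stop_ligandmsm("`lag` is required")
  ev <- sort(reversible_eigen(T_, pi)$values, decreasing = TRUE)
  lam <- ev[-1L]
  if (!is.null(n_timescales)) {
    lam <- lam[seq_len(min(n_timescales, length(lam)))]
  }
  ts <- rep(NA_real_, length(lam))
  ts[lam >= 1 - 1e-12] <- Inf
  ok <- lam > 0 & lam < 1 - 1e-12
  ts[ok] <- -lag / log(lam[ok])
  structure(list(eigenvalues = c(ev[1L], lam), timescales = ts, lag = lag),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("Spectral result at lag %g ns\n", x$lag))
  cat("  timescales (ns):", signif(x$timescales, 4), "\n")
  invisible(x)
}

#' Implied-timescale lag scan
#'
#' Re-counts and re-estimates the reversible model at each lag, restricted to
#' the set of microstates active at every lag, and reports the
#' implied-timescale curves.  The suggested Markovian lag is the smallest
#' tested lag whose slowest timescale differs from the next lag's by less
#' than 10% — the shortest lag at which the timescales no longer depend on
#' the lag.
#'
#' @param dtrajs List of [discrete_trajectory()] objects.
#' @param lags Numeric vector of at least two lag times (ns), each a positive
#'   multiple of the frame spacing.
#' @param n_timescales Number of timescales per lag (default 5).
#' @return A `lag_scan` object: a data frame `table` (lag, timescale index,
#'   tau_ns), the `suggested_lag`, and the per-lag models.
#' @export
lag_scan <- function(dtrajs, lags, n_timescales = 5L) {
  dtrajs <- as_dtraj_list(dtrajs)
  lags <- sort(unique(as.numeric(lags)))
  if (length(lags) < 2L) {
    stop_ligandmsm("`lags` must contain at least two distinct lag times")
  }
  counts <- lapply(lags, function(l) count_transitions(dtrajs, l))
  common <- Reduce(intersect, lapply(counts, function(cm) cm$active_set))
  if (length(common) < 2L) {
    stop_ligandmsm("fewer than two microstates are active at every lag")
  }
  models <- lapply(counts, function(cm) {
    sub <- cm$counts[common, common, drop = FALSE]
    act <- largest_connected_set(sub)
    cm$counts <- sub[act, act, drop = FALSE]
    cm$active_set <- seq_along(act)
    m <- estimate_reversible(cm)
    m$active_set <- common[act]
    m
  })
  tau2 <- vapply(models, function(m) {
    implied_timescales(m, n_timescales = 1L)$timescales[1L]
  }, 1)
  suggested <- NA_real_
  for (i in seq_len(length(lags) - 1L)) {
    if (is.finite(tau2[i]) && is.finite(tau2[i + 1L]) &&
        abs(tau2[i + 1L] - tau2[i]) < 0.10 * tau2[i]) {
      suggested <- lags[i]
      break
    }
  }
  tab <- do.call(rbind, lapply(seq_along(lags), function(i) {
    its <- implied_timescales(models[[i]], n_timescales = n_timescales)
    data.frame(lag_ns = lags[i],
               process = seq_along(its$timescales) + 1L,
               tau_ns = its$timescales)
  }))
  structure(list(table = tab, suggested_lag = suggested, lags = lags,
                 models = models),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat("Implied-timescale lag scan\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Suggested Markovian lag: %s ns\n",
              format(x$suggested_lag)))
  invisible(x)
}

#' Serialize / deserialize a transition model to JSON
#'
#' @param model A `transition_model`.
#' @param path File path.
#' @return `path` (write) or a `transition_model` (read).
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  jsonlite::write_json(
    list(T = model$T, pi = model$pi, lag = model$lag,
         active_set = model$active_set, loglik = model$loglik,
         frame_dt = model$frame_dt),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(T = as.matrix(x$T), pi = as.numeric(x$pi), lag = x$lag,
         active_set = as.integer(x$active_set), loglik = x$loglik,
         frame_dt = x$frame_dt),
    class = "transition_model"
  )
}
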