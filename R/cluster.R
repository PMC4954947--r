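#' k-centers (Gonzalez farthest-point) clustering
#'
#' Discretizes projected trajectories with the Gonzalez max-min algorithm:
#' the first center is a seeded uniform draw from the pooled frames, and each
#' subsequent center is the frame farthest from its nearest existing center.
#' The result is deterministic for a fixed seed and comes with the covering
#' radius (largest distance of any frame to its assigned center).
#'
#' @param data List of projected [feature_trajectory()] objects (or one).
#' @param k Number of geometric clusters, `1 <= k <=` total frames.
#' @param seed Integer seed for the first-center draw.
#' @return A `cluster_model` with fields `centers` (`k x d`), `k_geometric`,
#'   `n_microstates` (equal to `k` until [split_by_flag()] is applied),
#'   `flag_split_map` (`NULL` until then) and `covering_radius`.
#' @export
kcenters_fit <- function(data, k, seed) {
  data <- as_ftraj_list(data)
  X <- do.call(rbind, lapply(data, function(tr) tr$frames))
  k <- check_count(k, "k")
  seed <- check_seed(seed)
  n <- nrow(X)
  if (k > n) stop_ligandmsm("`k` exceeds the total number of frames")
  first <- withr::with_seed(seed, sample.int(n, 1L))
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, X[first, ])^2)
  if (k > 1L) {
    for (i in 2:k) {
      nxt <- which.max(d2)
      centers[i, ] <- X[nxt, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[nxt, ])^2))
    }
  }
  structure(
    list(centers = centers, k_geometric = k, n_microstates = k,
         flag_split_map = NULL, covering_radius = sqrt(max(d2))),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "k-centers model: %d geometric cluster(s), %d microstate(s), covering radius %.4g\n",
    x$k_geometric, x$n_microstates, x$covering_radius))
  invisible(x)
}

#' Assign frames to microstates
#'
#' Nearest-center assignment by Euclidean distance, ties broken towards the
#' lowest center index.  When the model carries a flag split map and
#' coordination `flags` are supplied, the (geometric cluster, flag) pair is
#' mapped to the final microstate id.
#'
#' @param model A `cluster_model`.
#' @param trajectory A projected [feature_trajectory()].
#' @param flags Optional [coordination_flags()] aligned with the trajectory.
#' @return A [discrete_trajectory()].
#' @export
assign_microstates <- function(model, trajectory, flags = NULL) {
  if (!inherits(model, "cluster_model")) stop_ligandmsm("`model` must be a cluster_model")
  if (!inherits(trajectory, "feature_trajectory")) {
    stop_ligandmsm("`trajectory` must be a feature_trajectory")
  }
  if (ncol(trajectory$frames) != ncol(model$centers)) {
    stop_ligandmsm("trajectory dimensionality does not match the cluster centers")
  }
  geo <- nearest_center(trajectory$frames, model$centers)
  states <- map_flagged_states(model, geo, flags, nrow(trajectory$frames))
  discrete_trajectory(states, frame_dt = trajectory$frame_dt,
                      n_microstates = model$n_microstates,
                      source = trajectory$source)
}

map_flagged_states <- function(model, geo, flags, T_) {
  if (is.null(model$flag_split_map)) {
    if (!is.null(flags) && length(flags) != T_) {
      stop_ligandmsm("`flags` length does not match the trajectory")
    }
    return(geo)
  }
  if (is.null(flags)) {
    flags <- rep(FALSE, T_)
  }
  if (length(flags) != T_) {
    stop_ligandmsm("`flags` length does not match the trajectory")
  }
  m <- model$flag_split_map
  key <- paste0(geo, ".", as.integer(as.logical(flags)))
  idx <- match(key, paste0(m$cluster, ".", as.integer(m$flag)))
  # a (cluster, flag) combination never observed in training falls back to
  # the cluster's base microstate
  fallback <- match(geo, m$cluster)
  idx[is.na(idx)] <- fallback[is.na(idx)]
  m$microstate[idx]
}

#' Split geometric clusters by ion-coordination flag
#'
#' Every geometric cluster observed with both flag values becomes two
#' microstates (coordinated / not coordinated); clusters with a single
#' observed flag value keep one id, so no empty microstates are created.
#' The total is `n_microstates = k_geometric + #(clusters with both flags)`.
#'
#' @param model A `cluster_model`.
#' @param assignments List of [discrete_trajectory()] objects produced from
#'   `model` (geometric assignments).
#' @param flags List of [coordination_flags()] aligned with `assignments`.
#' @return List with the updated `model` (carrying `flag_split_map`) and
#'   `assignments` reindexed to the final microstates.
#' @export
split_by_flag <- function(model, assignments, flags) {
  if (!inherits(model, "cluster_model")) stop_ligandmsm("`model` must be a cluster_model")
  assignments <- as_dtraj_list(assignments)
  if (!is.list(flags)) flags <- list(flags)
  if (length(flags) != length(assignments)) {
    stop_ligandmsm("`flags` must have one element per assignment trajectory")
  }
  for (i in seq_along(assignments)) {
    if (length(flags[[i]]) != length(assignments[[i]]$states)) {
      stop_ligandmsm("flag length mismatch with assignments")
    }
  }
  geo <- unlist(lapply(assignments, function(d) d$states))
  flg <- as.logical(unlist(flags))
  k <- model$k_geometric
  seen_true <- seen_false <- logical(k)
  seen_true[unique(geo[flg])] <- TRUE
  seen_false[unique(geo[!flg])] <- TRUE
  mixed <- which(seen_true & seen_false)
  # base microstate keeps the geometric id; the coordinated half of a mixed
  # cluster gets a fresh id appended after the geometric block
  map <- data.frame(
    cluster = c(seq_len(k), mixed),
    flag = c(seen_true & !seen_false, rep(TRUE, length(mixed))),
    microstate = c(seq_len(k), k + seq_along(mixed))
  )
  model$flag_split_map <- map
  model$n_microstates <- k + length(mixed)
  new_assign <- lapply(seq_along(assignments), function(i) {
    d <- assignments[[i]]
    states <- map_flagged_states(model, d$states, flags[[i]],
                                 length(d$states))
    discrete_trajectory(states, frame_dt = d$frame_dt,
                        n_microstates = model$n_microstates,
                        source = d$source)
  })
  list(model = model, assignments = new_assign)
}
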