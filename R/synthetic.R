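#' Feature-space embedding of discrete states
#'
#' Maps each discrete state to a centroid in an abstract feature space;
#' observed frames are centroids plus isotropic Gaussian noise.  This stands
#' in for the conformational degrees of freedom that real trajectories expose
#' through contact maps, and makes the discretization problem solvable by
#' construction when the centroid separation is large against the noise.
#'
#' @param centroids `n x m` numeric matrix, one row per discrete state.
#' @param noise_sd Isotropic Gaussian noise standard deviation, `>= 0`.
#' @return A `state_embedding` object.
#' @export
state_embedding <- function(centroids, noise_sd) {
  centroids <- as.matrix(centroids)
  if (!is.numeric(centroids) || anyNA(centroids)) {
    stop_ligandmsm("`centroids` must be a numeric matrix without NA")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_ligandmsm("`noise_sd` must be a single number >= 0")
  }
  structure(list(centroids = centroids, noise_sd = noise_sd),
            class = "state_embedding")
}

#' Ground-truth kinetic system
#'
#' Bundles a rate matrix, a feature-space embedding and the identity of the
#' bulk (ligand free in solution) and bound states, plus the frame spacing and
#' optional box metadata used to convert single-copy binding times into
#' bimolecular rate constants.  Systems built this way have analytic
#' stationary distributions, lag transition matrices and mean first passage
#' times ([exact_stationary()], [exact_transition_matrix()], [exact_mfpt()]),
#' so every downstream estimate can be compared against an exact value.
#'
#' @param rate_matrix A [rate_matrix()].
#' @param embedding A [state_embedding()] with one centroid per state.
#' @param bulk_state,bound_state 1-based indices; must differ.
#' @param frame_dt Frame spacing in ns.
#' @param box_volume Optional simulation-box volume in litres.
#' @param n_ligand_copies Optional number of ligand copies per box.
#' @return A `ground_truth_system` object.
#' @export
ground_truth_system <- function(rate_matrix, embedding, bulk_state, bound_state,
                                frame_dt, box_volume = NULL,
                                n_ligand_copies = NULL) {
  rate_matrix <- as_rate_matrix(rate_matrix)
  if (!inherits(embedding, "state_embedding")) {
    stop_ligandmsm("`embedding` must be a state_embedding")
  }
  n <- nrow(rate_matrix)
  if (nrow(embedding$centroids) != n) {
    stop_ligandmsm("embedding must have one centroid per state")
  }
  bulk_state <- check_count(bulk_state, "bulk_state")
  bound_state <- check_count(bound_state, "bound_state")
  if (bulk_state > n || bound_state > n) {
    stop_ligandmsm("bulk/bound state index out of range")
  }
  if (bulk_state == bound_state) {
    stop_ligandmsm("`bulk_state` and `bound_state` must differ")
  }
  check_scalar_positive(frame_dt, "frame_dt")
  if (!is.null(box_volume)) check_scalar_positive(box_volume, "box_volume")
  if (!is.null(n_ligand_copies)) check_count(n_ligand_copies, "n_ligand_copies")
  structure(
    list(rate_matrix = rate_matrix, embedding = embedding,
         bulk_state = bulk_state, bound_state = bound_state,
         frame_dt = frame_dt, box_volume = box_volume,
         n_ligand_copies = n_ligand_copies),
    class = "ground_truth_system"
  )
}

#' @export
print.ground_truth_system <- function(x, ...) {
  cat(sprintf(
    "Ground-truth system: %d states, bulk = %d, bound = %d, frame_dt = %g ns\n",
    nrow(x$rate_matrix), x$bulk_state, x$bound_state, x$frame_dt))
  if (!is.null(x$box_volume)) {
    cat(sprintf("  concentration: %g M\n",
                concentration_from_box(x$n_ligand_copies %||% 1L, x$box_volume)))
  }
  invisible(x)
}

# exact Gillespie simulation of one trajectory, discretized on the frame grid
sample_ctmc_one <- function(K, frame_dt, n_frames, s0) {
  n <- nrow(K)
  exit <- -diag(K)
  t_end <- (n_frames - 1L) * frame_dt
  cap <- 64L
  entry_times <- numeric(cap)
  entry_states <- integer(cap)
  k <- 1L
  entry_times[1L] <- 0
  entry_states[1L] <- s0
  t <- 0
  s <- s0
  repeat {
    r <- exit[s]
    if (r <= 0) break  # absorbing state
    t <- t + rexp(1L, r)
    if (t > t_end) break
    p <- K[s, ]
    p[s] <- 0
    s <- sample.int(n, 1L, prob = p)
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(entry_times) <- cap
      length(entry_states) <- cap
    }
    entry_times[k] <- t
    entry_states[k] <- s
  }
  frame_times <- seq(0, by = frame_dt, length.out = n_frames)
  entry_states[findInterval(frame_times, entry_times[seq_len(k)])]
}

#' Sample discretized continuous-time Markov jump trajectories
#'
#' Simulates exact Gillespie dynamics of the system's rate matrix and records
#' the state at every multiple of `frame_dt`, mimicking how molecular-dynamics
#' trajectories are saved on a fixed frame grid.  Initial states are drawn
#' from the exact stationary distribution unless `start_state` is given.
#'
#' @param system A [ground_truth_system()].
#' @param n_traj Number of independent trajectories.
#' @param n_frames Frames per trajectory (`>= 2`).
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @param start_state Optional fixed initial state for all trajectories
#'   (e.g. the bulk state for binding-time experiments).
#' @return List of [discrete_trajectory()] objects.  If any state is
#'   absorbing (zero exit rate) the list carries an `absorbing_states`
#'   attribute naming them.
#' @export
sample_ctmc_trajectories <- function(system, n_traj, n_frames, seed,
                                     start_state = NULL) {
  if (!inherits(system, "ground_truth_system")) {
    stop_ligandmsm("`system` must be a ground_truth_system")
  }
  n_traj <- check_count(n_traj, "n_traj")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  seed <- check_seed(seed)
  K <- unclass(system$rate_matrix)
  n <- nrow(K)
  if (!is.null(start_state)) {
    start_state <- check_count(start_state, "start_state")
    if (start_state > n) stop_ligandmsm("`start_state` out of range")
  }
  absorbing <- which(-diag(K) <= 0)
  pi0 <- if (is.null(start_state) && length(absorbing) == 0L) {
    exact_stationary(system$rate_matrix)
  } else if (is.null(start_state)) {
    # stationary draw is ill-defined with absorbing states; start uniformly
    rep(1 / n, n)
  }
  out <- withr::with_seed(seed, {
    lapply(seq_len(n_traj), function(i) {
      s0 <- if (is.null(start_state)) sample.int(n, 1L, prob = pi0) else start_state
      discrete_trajectory(sample_ctmc_one(K, system$frame_dt, n_frames, s0),
                          frame_dt = system$frame_dt, n_microstates = n,
                          source = c(run = i, ligand = 1L))
    })
  })
  if (length(absorbing)) {
    attr(out, "absorbing_states") <- absorbing
  }
  out
}

#' Embed a discrete trajectory in feature space
#'
#' Replaces each state index by its embedding centroid and adds isotropic
#' Gaussian observation noise, producing the synthetic analogue of a
#' featurized trajectory.
#'
#' @param dtraj A [discrete_trajectory()] or plain integer vector of 1-based
#'   state indices.
#' @param embedding A [state_embedding()].
#' @param frame_dt Frame spacing in ns (taken from `dtraj` when available).
#' @param seed Integer seed for the noise draw.
#' @return A [feature_trajectory()].
#' @export
embed_states <- function(dtraj, embedding, frame_dt = NULL, seed = 0L) {
  if (!inherits(embedding, "state_embedding")) {
    stop_ligandmsm("`embedding` must be a state_embedding")
  }
  if (inherits(dtraj, "discrete_trajectory")) {
    frame_dt <- frame_dt %||% dtraj$frame_dt
    source <- dtraj$source
    states <- dtraj$states
  } else {
    source <- NULL
    states <- as.integer(dtraj)
  }
  if (is.null(frame_dt)) stop_ligandmsm("`frame_dt` is required")
  n <- nrow(embedding$centroids)
  if (any(states < 1L) || any(states > n)) {
    stop_ligandmsm("state index out of range for the embedding")
  }
  seed <- check_seed(seed)
  frames <- embedding$centroids[states, , drop = FALSE]
  if (embedding$noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      matrix(rnorm(length(frames), sd = embedding$noise_sd),
             nrow = nrow(frames))
    })
    frames <- frames + noise
  }
  feature_trajectory(frames, frame_dt = frame_dt, source = source)
}

#' Benchmark ground-truth systems
#'
#' Fixed, documented systems used throughout the test suite:
#'
#' * `"twostate"` — slow two-state exchange (bulk <-> bound, mean dwell
#'   times 20 ns and 50 ns) with two well-separated 2-D centroids; used for
#'   TICA separation and standard-state consistency checks.
#' * `"binding5"` — five states mirroring the structure typical of
#'   free-ligand binding runs: a dominant bulk state, an off-pathway
#'   interface state that only exchanges with bulk, two short-lived
#'   on-pathway intermediates, and a long-lived bound state (20 ns mean
#'   residence versus a 6.7 ns mean bulk dwell).  Box metadata gives a
#'   12 mM single-copy ligand concentration.
#' * `"metastable_blocks"` — six states in two weakly coupled three-state
#'   blocks (inter-block rate 0.002/ns against 0.5/ns inside), the standard
#'   ground truth for macrostate lumping.
#'
#' @param name One of `"twostate"`, `"binding5"`, `"metastable_blocks"`.
#' @return A [ground_truth_system()].
#' @export
msm_preset <- function(name = c("twostate", "binding5", "metastable_blocks")) {
  name <- match.arg(name)
  switch(name,
    twostate = {
      K <- rate_matrix(matrix(c(-0.05, 0.05,
                                 0.02, -0.02), 2, byrow = TRUE),
                       state_names = c("bulk", "bound"))
      emb <- state_embedding(rbind(c(-2, 0), c(2, 0)), noise_sd = 0.4)
      ground_truth_system(K, emb, bulk_state = 1L, bound_state = 2L,
                          frame_dt = 0.1,
                          box_volume = 1 / (.N_AVOGADRO * 0.003),
                          n_ligand_copies = 1L)
    },
    binding5 = {
      K <- matrix(0, 5, 5)
      # 1 bulk, 2 interface (off-pathway), 3 approach, 4 pre-bound, 5 bound
      K[1, 2] <- 0.10; K[2, 1] <- 1.0
      K[1, 3] <- 0.05; K[3, 1] <- 2.0
      K[3, 4] <- 1.0;  K[4, 3] <- 1.0
      K[4, 5] <- 1.0;  K[5, 4] <- 0.05
      diag(K) <- -rowSums(K)
      K <- rate_matrix(K, state_names = c("bulk", "interface", "approach",
                                          "prebound", "bound"))
      emb <- state_embedding(rbind(c(0, 0, 0),
                                   c(4.5, 0, 0),
                                   c(0, 5, 0),
                                   c(0, 0, 6),
                                   c(5, 5, 5)),
                             noise_sd = 0.4)
      ground_truth_system(K, emb, bulk_state = 1L, bound_state = 5L,
                          frame_dt = 0.1,
                          box_volume = 1 / (.N_AVOGADRO * 0.012),
                          n_ligand_copies = 1L)
    },
    metastable_blocks = {
      K <- matrix(0, 6, 6)
      for (blk in list(1:3, 4:6)) {
        for (i in blk) for (j in blk) if (i != j) K[i, j] <- 0.5
      }
      K[3, 4] <- 0.002; K[4, 3] <- 0.002
      diag(K) <- 0
      diag(K) <- -rowSums(K)
      K <- rate_matrix(K)
      emb <- state_embedding(rbind(c(0, 0, 0), c(1.8, 0, 0), c(0, 1.8, 0),
                                   c(8, 8, 8), c(9.8, 8, 8), c(8, 9.8, 8)),
                             noise_sd = 0.3)
      ground_truth_system(K, emb, bulk_state = 1L, bound_state = 6L,
                          frame_dt = 0.1)
    })
}
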