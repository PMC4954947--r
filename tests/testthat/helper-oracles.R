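# Independent oracles used across the suite.  Each is a deliberately
# different route to the same quantity as the implementation under test:
# generic numerical optimization instead of the fixed point, Monte-Carlo
# sampling instead of linear solves, matrix-power reachability instead of
# graph library calls.

# Constrained-likelihood oracle for the reversible transition-matrix MLE:
# parameterize the symmetric auxiliary variables x_ij = exp(theta_ij)
# (upper triangle incl. diagonal; the likelihood is invariant to the overall
# scale of x) and maximize sum C_ij log(x_ij / x_i.) with BFGS and an
# analytic gradient.
oracle_reversible_mle <- function(C) {
  n <- nrow(C)
  up <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  Ci <- rowSums(C)
  sym <- C + t(C)
  unpack <- function(theta) {
    x <- matrix(0, n, n)
    x[up] <- exp(theta)
    x + t(x) - diag(diag(x))
  }
  nll_with_grad <- function(theta) {
    x <- unpack(theta)
    xi <- rowSums(x)
    val <- -sum(C[C > 0] * log((x / xi)[C > 0]))
    g <- sym / x - outer(Ci / xi, rep(1, n)) - outer(rep(1, n), Ci / xi)
    diag(g) <- diag(C) / diag(x) - Ci / xi
    g[x == 0] <- 0
    attr(val, "gradient") <- -(g * x)[up]
    val
  }
  theta0 <- log(pmax(sym[up] / sum(sym), 1e-8))
  res <- stats::nlm(nll_with_grad, theta0, gradtol = 1e-14, steptol = 1e-15,
                    iterlim = 10000)
  x <- unpack(res$estimate)
  x / rowSums(x)
}

# Monte-Carlo first passage times of a discrete-time chain, vectorized over
# walkers; returns passage times in the chain's time unit (steps * lag).
mc_mfpt_chain <- function(T_, lag, start, target, n_runs, seed,
                          max_steps = 1e6) {
  n <- nrow(T_)
  cum <- t(apply(T_, 1, cumsum))
  withr::with_seed(seed, {
    state <- rep(as.integer(start), length.out = n_runs)
    steps <- integer(n_runs)
    alive <- !(state %in% target)
    k <- 0L
    while (any(alive)) {
      k <- k + 1L
      if (k > max_steps) stop("MC first-passage did not absorb")
      u <- runif(sum(alive))
      idx <- which(alive)
      nxt <- integer(length(idx))
      for (s in unique(state[idx])) {
        sel <- state[idx] == s
        nxt[sel] <- findInterval(u[sel], cum[s, ]) + 1L
      }
      state[idx] <- nxt
      steps[idx] <- k
      alive[idx] <- !(nxt %in% target)
    }
    steps * lag
  })
}

# Monte-Carlo first passage times of a continuous-time jump process
# (exact Gillespie, vectorized over runs).
mc_mfpt_ctmc <- function(K, start, target, n_runs, seed, max_jumps = 1e6) {
  n <- nrow(K)
  exit <- -diag(K)
  jump_prob <- K
  diag(jump_prob) <- 0
  jump_prob <- jump_prob / pmax(rowSums(jump_prob), .Machine$double.eps)
  cum <- t(apply(jump_prob, 1, cumsum))
  withr::with_seed(seed, {
    state <- rep(as.integer(start), length.out = n_runs)
    t_hit <- numeric(n_runs)
    alive <- !(state %in% target)
    k <- 0L
    while (any(alive)) {
      k <- k + 1L
      if (k > max_jumps) stop("CTMC first-passage did not absorb")
      idx <- which(alive)
      t_hit[idx] <- t_hit[idx] + rexp(length(idx), exit[state[idx]])
      u <- runif(length(idx))
      nxt <- integer(length(idx))
      for (s in unique(state[idx])) {
        sel <- state[idx] == s
        nxt[sel] <- findInterval(u[sel], cum[s, ]) + 1L
      }
      state[idx] <- nxt
      alive[idx] <- !(nxt %in% target)
    }
    t_hit
  })
}

# Brute-force strongly connected components from matrix-power reachability.
oracle_scc_membership <- function(A) {
  n <- nrow(A)
  R <- (A > 0) | diag(n) > 0
  for (i in seq_len(n)) {
    R <- R | (R %*% R) > 0
  }
  mutual <- R & t(R)
  membership <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[mutual[i, ]] <- comp
    }
  }
  membership
}

# Test fixture: count model straight from a count matrix.
make_count_model <- function(C, lag = 1, frame_dt = 1) {
  structure(
    list(counts = C, lag = lag, counting_mode = "sliding",
         active_set = largest_connected_set(C), frame_dt = frame_dt),
    class = "count_model"
  )
}

# Test fixture: transition model straight from a stochastic matrix.
make_transition_model <- function(T_, lag = 1, pi = NULL, frame_dt = 1) {
  if (is.null(pi)) pi <- stationary_distribution(T_)
  structure(
    list(T = T_, pi = pi, lag = lag, active_set = seq_len(nrow(T_)),
         loglik = NA_real_, frame_dt = frame_dt),
    class = "transition_model"
  )
}

# Ground-truth tau_2 of a preset at a given lag, from the exact propagator.
exact_tau2 <- function(system, lag) {
  ev <- sort(Re(eigen(exact_transition_matrix(system$rate_matrix, lag))$values),
             decreasing = TRUE)
  -lag / log(ev[2])
}

# Embedded feature trajectories for a preset (the synthetic stand-in for a
# featurized trajectory ensemble).
preset_features <- function(system, n_traj, n_frames, seed) {
  dtrajs <- sample_ctmc_trajectories(system, n_traj, n_frames, seed = seed)
  features <- lapply(seq_along(dtrajs), function(i) {
    embed_states(dtrajs[[i]], system$embedding, seed = seed + i)
  })
  list(dtrajs = dtrajs, features = features)
}
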