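dtraj <- function(states, n = max(states), frame_dt = 1) {
  discrete_trajectory(states, frame_dt = frame_dt, n_microstates = n)
}

test_that("sliding-window counts enumerate lagged pairs within trajectories", {
  cm <- count_transitions(list(dtraj(c(1, 1, 2, 2))), lag = 1)
  expect_equal(cm$counts, matrix(c(1, 1, 0, 1), 2, byrow = TRUE))
  cm2 <- count_transitions(list(dtraj(c(1, 2, 1, 2, 1))), lag = 2)
  expect_equal(cm2$counts, matrix(c(2, 0, 0, 1), 2, byrow = TRUE))
  # counts are additive over trajectories and never cross boundaries
  a <- dtraj(c(1, 1, 2), n = 2)
  b <- dtraj(c(2, 1, 1), n = 2)
  both <- count_transitions(list(a, b), lag = 1)
  expect_equal(both$counts,
               count_transitions(list(a), lag = 1)$counts +
                 count_transitions(list(b), lag = 1)$counts)
  expect_error(count_transitions(list(dtraj(c(1, 2))), lag = 5),
               "longer than the lag")
})

test_that("largest connected set matches brute-force reachability", {
  expect_equal(largest_connected_set(matrix(c(5, 1, 1, 5), 2)), c(1L, 2L))
  # disconnected states: size tie broken by counts, then lowest index
  expect_equal(largest_connected_set(matrix(c(5, 0, 0, 9), 2)), 2L)
  expect_equal(largest_connected_set(matrix(c(5, 0, 0, 5), 2)), 1L)
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(4:9, 1)
      C <- matrix(rbinom(n * n, 1, 0.25) * rpois(n * n, 3), n)
      act <- largest_connected_set(C)
      mem <- oracle_scc_membership(C)
      sizes <- tabulate(mem)
      expect_equal(length(act), max(sizes))
      expect_true(all(mem[act] == mem[act[1]]))
    }
  })
})

test_that("reversible MLE reduces to row normalization for symmetric counts", {
  m <- estimate_reversible(make_count_model(matrix(c(9, 1, 1, 9), 2)))
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2), tolerance = 1e-10)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("reversible MLE matches an independent constrained optimizer", {
  C <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  m <- estimate_reversible(make_count_model(C))
  expect_lt(max(abs(m$T - oracle_reversible_mle(C))), 1e-8)
  # detailed balance and stochasticity hold to numerical precision
  expect_lt(max(abs(m$pi * m$T - t(m$pi * m$T))), 1e-8)
  expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
  # constrained optimum cannot beat the unconstrained row-normalized MLE
  T_free <- C / rowSums(C)
  expect_lte(m$loglik, sum(C[C > 0] * log(T_free[C > 0])) + 1e-9)
})

test_that("reversible MLE recovers the matrix behind long simulated counts", {
  # reversible by construction: row-normalized symmetric weights
  x <- matrix(c(9.0, 0.8, 0.2,
                0.8, 8.0, 1.5,
                0.2, 1.5, 8.0), 3, byrow = TRUE)
  T_true <- x / rowSums(x)
  states <- withr::with_seed(20, {
    s <- integer(1e6)
    s[1] <- 1L
    u <- runif(1e6)
    cum <- t(apply(T_true, 1, cumsum))
    for (t in 2:1e6) s[t] <- findInterval(u[t], cum[s[t - 1L], ]) + 1L
    s
  })
  cm <- count_transitions(list(dtraj(states, n = 3)), lag = 1)
  m <- estimate_reversible(cm)
  expect_lt(max(abs(m$T - T_true)), 0.01)
})

test_that("estimator is invariant to trajectory order and state relabeling", {
  dat <- preset_features(msm_preset("binding5"), n_traj = 8, n_frames = 300,
                         seed = 21)
  d <- dat$dtrajs
  m1 <- estimate_reversible(count_transitions(d, lag = 1))
  m2 <- estimate_reversible(count_transitions(rev(d), lag = 1))
  expect_equal(m1$T, m2$T, tolerance = 1e-12)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  relabeled <- lapply(d, function(x) dtraj(perm[x$states], n = 5,
                                           frame_dt = x$frame_dt))
  m3 <- estimate_reversible(count_transitions(relabeled, lag = 1))
  # row p of m3 is relabeled state p = perm of the original state, so
  # T1[i, j] must equal T3[perm[i], perm[j]]
  expect_equal(m3$T[perm[m1$active_set], perm[m1$active_set]], m1$T,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("stationary distributions solve pi T = pi", {
  expect_equal(stationary_distribution(matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                              byrow = TRUE)),
               c(2 / 3, 1 / 3))
  doubly <- matrix(c(0.5, 0.3, 0.2,
                     0.2, 0.5, 0.3,
                     0.3, 0.2, 0.5), 3, byrow = TRUE)
  expect_equal(stationary_distribution(doubly), rep(1 / 3, 3))
  expect_error(stationary_distribution(diag(2)), "reducible")
})

test_that("implied timescales follow tau = -lag / log(lambda)", {
  T2 <- function(lam) matrix(c((1 + lam) / 2, (1 - lam) / 2,
                               (1 - lam) / 2, (1 + lam) / 2), 2, byrow = TRUE)
  its <- implied_timescales(make_transition_model(T2(exp(-1)), lag = 1))
  expect_equal(its$timescales[1], 1, tolerance = 1e-12)
  its2 <- implied_timescales(make_transition_model(T2(0.7), lag = 2))
  expect_equal(its2$timescales[1], -2 / log(0.7), tolerance = 1e-12)
  expect_equal(round(its2$timescales[1], 3), 5.607)
  # eigenvalues at 1 within tolerance are reported as infinite
  its3 <- implied_timescales(make_transition_model(T2(1 - 1e-14), lag = 1,
                                                   pi = c(0.5, 0.5)))
  expect_true(is.infinite(its3$timescales[1]))
  # non-positive eigenvalues have no defined timescale
  its4 <- implied_timescales(make_transition_model(T2(-0.2), lag = 1,
                                                   pi = c(0.5, 0.5)))
  expect_true(is.na(its4$timescales[1]))
})

test_that("lag scans flag Markovian data at the shortest lag", {
  sys <- msm_preset("twostate")
  d <- sample_ctmc_trajectories(sys, n_traj = 60, n_frames = 3000, seed = 22)
  sc <- lag_scan(d, lags = c(0.5, 1, 2, 4), n_timescales = 1)
  expect_equal(sc$suggested_lag, 0.5)
  tau2 <- sc$table$tau_ns[sc$table$process == 2]
  truth <- exact_tau2(sys, 1)
  expect_true(all(abs(tau2 - truth) / truth < 0.15))
  expect_error(lag_scan(d, lags = 2), "at least two")
})

test_that("hiding a fast process inflates timescales until the lag covers it", {
  # 3-state chain: states 1-2 exchange fast, state 3 slow; observing 1 and 2
  # as one lumped state breaks Markovianity at short lags
  K <- matrix(0, 3, 3)
  K[1, 2] <- 0.3; K[2, 1] <- 1.2
  K[2, 3] <- 2.0; K[3, 2] <- 0.3
  diag(K) <- -rowSums(K)
  emb <- state_embedding(rbind(0, 1, 2), noise_sd = 0)
  sys <- ground_truth_system(rate_matrix(K), emb, bulk_state = 1,
                             bound_state = 3, frame_dt = 0.1)
  d <- sample_ctmc_trajectories(sys, n_traj = 100, n_frames = 2000, seed = 23)
  lumped <- lapply(d, function(x) {
    dtraj(ifelse(x$states == 3L, 2L, 1L), n = 2, frame_dt = x$frame_dt)
  })
  sc <- lag_scan(lumped, lags = c(0.2, 0.5, 1, 2, 4, 8), n_timescales = 1)
  tau2 <- sc$table$tau_ns[sc$table$process == 2]
  expect_gt(tau2[4], 1.2 * tau2[1])       # rises away from the frame spacing
  expect_gt(sc$suggested_lag, 0.2)        # shortest lag is rejected
})

test_that("transition models round-trip through JSON", {
  m <- estimate_reversible(make_count_model(matrix(c(40, 4, 6, 50), 2,
                                                   byrow = TRUE)))
  path <- withr::local_tempfile(fileext = ".json")
  write_transition_model(m, path)
  m2 <- read_transition_model(path)
  expect_equal(m2$T, m$T, ignore_attr = TRUE)
  expect_equal(m2$pi, m$pi)
  expect_equal(m2$active_set, m$active_set)
})
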