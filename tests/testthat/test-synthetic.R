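test_that("zero-rate systems stay in their start state and are flagged", {
  emb <- state_embedding(rbind(0, 1), noise_sd = 0)
  sys <- ground_truth_system(rate_matrix(matrix(0, 2, 2)), emb,
                             bulk_state = 1, bound_state = 2, frame_dt = 0.1)
  trajs <- sample_ctmc_trajectories(sys, n_traj = 3, n_frames = 50, seed = 1,
                                    start_state = 1)
  for (d in trajs) expect_equal(d$states, rep(1L, 50))
  expect_equal(attr(trajs, "absorbing_states"), c(1L, 2L))
})

test_that("sampled occupancies match the exact stationary distribution", {
  emb <- state_embedding(rbind(0, 1), noise_sd = 0)
  K <- rate_matrix(matrix(c(-1, 1, 1, -1), 2, byrow = TRUE))
  sys <- ground_truth_system(K, emb, bulk_state = 1, bound_state = 2,
                             frame_dt = 0.1)
  trajs <- sample_ctmc_trajectories(sys, n_traj = 100, n_frames = 10000,
                                    seed = 2)
  s <- unlist(lapply(trajs, function(d) d$states))
  occ <- mean(s == 1L)
  # relaxation time 0.5 ns -> integrated autocorrelation ~5 frames at 0.1 ns
  n_eff <- length(s) / 10
  se <- sqrt(0.25 / n_eff)
  expect_lt(abs(occ - 0.5), 3 * se)
})

test_that("mean dwell times match the reciprocal exit rate", {
  emb <- state_embedding(rbind(0, 1), noise_sd = 0)
  K <- rate_matrix(matrix(c(-2, 2, 1, -1), 2, byrow = TRUE))
  sys <- ground_truth_system(K, emb, bulk_state = 1, bound_state = 2,
                             frame_dt = 0.01)
  trajs <- sample_ctmc_trajectories(sys, n_traj = 30, n_frames = 10000, seed = 3)
  dwells <- unlist(lapply(trajs, function(d) {
    r <- rle(d$states)
    # interior visits to state 1 only (first/last runs are censored)
    keep <- r$values == 1L
    if (length(r$lengths) >= 2) keep[c(1, length(keep))] <- FALSE
    r$lengths[keep] * d$frame_dt
  }))
  expect_gt(length(dwells), 500)
  se <- sd(dwells) / sqrt(length(dwells))
  # discretization adds ~frame_dt/2 to each observed dwell
  expect_lt(abs(mean(dwells) - (0.5 + 0.005)), 3 * se)
})

test_that("empirical transition frequencies converge to the exact propagator", {
  sys <- msm_preset("twostate")
  trajs <- sample_ctmc_trajectories(sys, n_traj = 50, n_frames = 4000, seed = 4)
  lag_frames <- 10L
  lag <- lag_frames * sys$frame_dt
  T_exact <- exact_transition_matrix(sys$rate_matrix, lag)
  s <- lapply(trajs, function(d) d$states)
  C <- matrix(0, 2, 2)
  for (x in s) {
    i <- x[seq_len(length(x) - lag_frames)]
    j <- x[(lag_frames + 1):length(x)]
    C <- C + matrix(tabulate((j - 1L) * 2L + i, 4), 2, 2)
  }
  T_emp <- C / rowSums(C)
  expect_lt(max(abs(T_emp - T_exact)), 5 / sqrt(sum(C)))
})

test_that("generators are bit-reproducible for a fixed seed", {
  sys <- msm_preset("binding5")
  a <- sample_ctmc_trajectories(sys, 5, 100, seed = 9)
  b <- sample_ctmc_trajectories(sys, 5, 100, seed = 9)
  expect_identical(a, b)
  fa <- embed_states(a[[1]], sys$embedding, seed = 5)
  fb <- embed_states(b[[1]], sys$embedding, seed = 5)
  expect_identical(fa$frames, fb$frames)
  cfg <- brownian_config(box_edge = 50, diffusion_coeff = 1,
                         well_center = c(25, 25, 25), well_depth = 2,
                         well_radius = 6, receptor_atoms = rbind(c(25, 25, 25)),
                         dt = 0.05, seed = 21)
  expect_identical(brownian_binding_trajectories(cfg, 2, 50),
                   brownian_binding_trajectories(cfg, 2, 50))
})

test_that("state embedding adds calibrated isotropic noise", {
  emb0 <- state_embedding(rbind(c(1, 2), c(3, 4)), noise_sd = 0)
  f <- embed_states(c(1, 2, 1), emb0, frame_dt = 0.1, seed = 1)
  expect_equal(f$frames, rbind(c(1, 2), c(3, 4), c(1, 2)))
  emb1 <- state_embedding(rbind(c(0, 0)), noise_sd = 1)
  f1 <- embed_states(rep(1L, 1e5), emb1, frame_dt = 0.1, seed = 2)
  sds <- apply(f1$frames, 2, sd)
  expect_true(all(sds > 0.97 & sds < 1.03))
  # symmetric two-state centroids at +-e1 average out at equal occupancy
  emb2 <- state_embedding(rbind(c(1, 0), c(-1, 0)), noise_sd = 0.3)
  f2 <- embed_states(rep(c(1L, 2L), 5e3), emb2, frame_dt = 0.1, seed = 3)
  expect_lt(abs(mean(f2$frames[, 1])), 0.02)
  expect_error(embed_states(c(1, 3), emb2, frame_dt = 0.1, seed = 1),
               "out of range")
})

test_that("Brownian trajectories respect walls and free-diffusion statistics", {
  cfg <- brownian_config(box_edge = 200, diffusion_coeff = 1,
                         well_center = c(100, 100, 100), well_depth = 0,
                         well_radius = 5, receptor_atoms = rbind(c(100, 100, 100)),
                         dt = 0.02, seed = 31)
  trajs <- brownian_binding_trajectories(cfg, n_traj = 200, n_frames = 200)
  xyz <- do.call(rbind, lapply(trajs, function(t) t$ligand))
  expect_true(all(xyz >= 0 & xyz <= 200))
  # MSD over a 50-step lag in a box far larger than the excursions
  lag <- 50L
  msd <- mean(vapply(trajs, function(t) {
    d <- t$ligand[(lag + 1):200, ] - t$ligand[1:(200 - lag), ]
    mean(rowSums(d^2))
  }, 1))
  expected <- 6 * cfg$diffusion_coeff * lag * cfg$dt
  expect_lt(abs(msd - expected) / expected, 0.10)
})

test_that("an attractive well enriches ligand density inside it", {
  base <- list(box_edge = 40, diffusion_coeff = 1,
               well_center = c(20, 20, 20), well_radius = 6,
               receptor_atoms = rbind(c(20, 20, 20)), dt = 0.05, seed = 32)
  frac_inside <- function(depth) {
    cfg <- do.call(brownian_config, c(base, list(well_depth = depth)))
    trajs <- brownian_binding_trajectories(cfg, n_traj = 20, n_frames = 2000)
    mean(vapply(trajs, function(t) {
      r <- sqrt(rowSums(sweep(t$ligand, 2, cfg$well_center)^2))
      mean(r < cfg$well_radius)
    }, 1))
  }
  expect_gt(frac_inside(5), frac_inside(0))
})

test_that("Brownian configuration rejects unresolvable time steps", {
  expect_error(
    brownian_config(box_edge = 50, diffusion_coeff = 10,
                    well_center = c(25, 25, 25), well_depth = 1,
                    well_radius = 2, receptor_atoms = rbind(c(25, 25, 25)),
                    dt = 0.5, seed = 1),
    "time step too large")
})

test_that("benchmark presets are resolvable and carry consistent metadata", {
  for (name in c("twostate", "binding5", "metastable_blocks")) {
    sys <- msm_preset(name)
    cen <- sys$embedding$centroids
    dmin <- min(dist(cen))
    expect_gt(dmin, 4 * sys$embedding$noise_sd)
    expect_true(sys$bulk_state != sys$bound_state)
    expect_lt(max(abs(rowSums(sys$rate_matrix))), 1e-12)
  }
  sys <- msm_preset("binding5")
  # dominant bulk state and long-lived bound state
  pi <- exact_stationary(sys$rate_matrix)
  expect_equal(which.max(pi), sys$bulk_state)
  K <- unclass(sys$rate_matrix)
  expect_gt(1 / -K[sys$bound_state, sys$bound_state],
            1 / -K[sys$bulk_state, sys$bulk_state])
  expect_equal(concentration_from_box(1, sys$box_volume), 0.012,
               tolerance = 1e-6)
})
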