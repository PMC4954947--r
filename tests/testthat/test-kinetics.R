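test_that("PCCA+ lumping is exact on trivially metastable systems", {
  T2 <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE)
  macro <- pcca_lump(make_transition_model(T2), 2)
  expect_equal(sort(unique(macro$crisp_assignment)), 1:2)
  expect_equal(length(unique(macro$crisp_assignment)), 2L)
  expect_equal(rowSums(macro$memberships), c(1, 1), tolerance = 1e-12)
})

test_that("PCCA+ recovers the two blocks of the block-metastable benchmark", {
  sys <- msm_preset("metastable_blocks")
  T_ <- exact_transition_matrix(sys$rate_matrix, 0.5)
  expect_lt(max(T_[1:3, 4:6]), 0.01)  # weak inter-block coupling
  macro <- pcca_lump(make_transition_model(T_, lag = 0.5), 2)
  blocks <- macro$crisp_assignment
  expect_equal(length(unique(blocks[1:3])), 1L)
  expect_equal(length(unique(blocks[4:6])), 1L)
  expect_true(blocks[1] != blocks[4])
  expect_equal(sum(macro$macro_pi), 1, tolerance = 1e-12)
})

test_that("PCCA+ memberships are a valid soft partition on random reversible models", {
  withr::with_seed(25, {
    for (rep in 1:5) {
      n <- sample(5:12, 1)
      x <- matrix(runif(n * n, 0.05, 1), n)
      x <- x + t(x)
      T_ <- x / rowSums(x)
      macro <- pcca_lump(make_transition_model(T_), sample(2:3, 1))
      expect_true(all(macro$memberships >= 0 & macro$memberships <= 1))
      expect_equal(rowSums(macro$memberships), rep(1, n), tolerance = 1e-9)
    }
  })
})

test_that("bulk and bound are identified from contact scores", {
  # the spectrum of this benchmark has one slow process (bulk <-> bound
  # exchange; the intermediates live well below the lag time), so two
  # macrostates resolve the metastability
  sys <- msm_preset("binding5")
  dat <- preset_features(sys, n_traj = 40, n_frames = 1500, seed = 26)
  cfg <- validate_config(list(n_clusters = 30, msm_lag = 2,
                              n_macrostates = 2, concentration = 0.012,
                              seed = 26, bootstrap = NULL))
  fit <- ligandmsm:::fit_msm_pipeline(dat$features, cfg)
  macro <- fit$macro
  expect_equal(macro$labels[macro$bulk], "bulk")
  expect_equal(macro$labels[macro$bound], "bound")
  # the bound macrostate carries the bound population realized in this
  # finite sample; the bulk macrostate absorbs bulk plus the fleeting
  # intermediates
  truth_states <- unlist(lapply(dat$dtrajs, function(d) d$states))
  occ_bound <- mean(truth_states == sys$bound_state)
  expect_equal(macro$macro_pi[macro$bound], occ_bound, tolerance = 0.05)
  expect_gt(macro$macro_pi[macro$bulk],
            mean(truth_states == sys$bulk_state) - 0.05)
  # degenerate scores cannot be labelled
  expect_error(identify_bulk_bound(macro, rep(0, nrow(macro$memberships))),
               "degenerate")
})

test_that("two-macrostate systems label a bulk/bound pair", {
  T2 <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE)
  macro <- pcca_lump(make_transition_model(T2), 2)
  macro <- identify_bulk_bound(macro, c(0, 7))
  expect_setequal(macro$labels, c("bulk", "bound"))
})

test_that("MFPT solves the lag-weighted hitting-time system", {
  T_ <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE)
  m <- make_transition_model(T_, lag = 1, pi = c(0.5, 0.5))
  expect_equal(mfpt(m, 1, 2), 10)  # geometric waiting time 1/0.1
  expect_equal(mfpt(m, 2, 2), 0)
  expect_error(mfpt(m, 1, integer()), "nonempty")
})

test_that("MFPT matches Monte-Carlo first passage sampling on a chain", {
  x <- matrix(0, 4, 4)
  x[1, 2] <- x[2, 3] <- x[3, 4] <- 0.1
  x <- x + t(x)
  diag(x) <- c(0.8, 0.7, 0.75, 0.9)
  T_ <- x / rowSums(x)
  m <- make_transition_model(T_, lag = 2)
  times <- mc_mfpt_chain(T_, lag = 2, start = 1, target = 4, n_runs = 2e4,
                         seed = 27)
  ci <- mean(times) + c(-1, 1) * 2.576 * sd(times) / sqrt(length(times))
  est <- mfpt(m, 1, 4)
  expect_gt(est, ci[1])
  expect_lt(est, ci[2])
})

test_that("committors satisfy boundary, symmetry and sampling checks", {
  # symmetric 3-state chain A - I - B
  T_ <- matrix(c(0.8, 0.2, 0,
                 0.1, 0.8, 0.1,
                 0, 0.2, 0.8), 3, byrow = TRUE)
  m <- make_transition_model(T_)
  q <- committor(m, A = 1, B = 3)
  expect_equal(q[1], 0)
  expect_equal(q[3], 1)
  expect_equal(q[2], 0.5, tolerance = 1e-12)
  expect_error(committor(m, A = 1, B = 1), "disjoint")
  # biased chain against brute-force trajectory statistics
  Tb <- matrix(c(0.7, 0.3, 0,
                 0.1, 0.6, 0.3,
                 0, 0.2, 0.8), 3, byrow = TRUE)
  # make it reversible for the model constructor: it already is a chain
  mb <- make_transition_model(Tb)
  qb <- committor(mb, A = 1, B = 3)
  hits <- withr::with_seed(28, {
    n_runs <- 2e4
    cum <- t(apply(Tb, 1, cumsum))
    state <- rep(2L, n_runs)
    alive <- rep(TRUE, n_runs)
    hit_b <- logical(n_runs)
    while (any(alive)) {
      idx <- which(alive)
      u <- runif(length(idx))
      nxt <- integer(length(idx))
      for (s in unique(state[idx])) {
        sel <- state[idx] == s
        nxt[sel] <- findInterval(u[sel], cum[s, ]) + 1L
      }
      state[idx] <- nxt
      hit_b[idx[nxt == 3L]] <- TRUE
      alive[idx] <- !(nxt %in% c(1L, 3L))
    }
    hit_b
  })
  se <- sqrt(qb[2] * (1 - qb[2]) / length(hits))
  expect_lt(abs(mean(hits) - qb[2]), 3 * se)
})

test_that("rate constants and free energies follow the standard-state relations", {
  kin <- rates_from_mfpt(mfpt_on = 100, mfpt_off = 50, concentration = 0.012)
  expect_equal(kin$kon, 1 / (100e-9 * 0.012))
  expect_equal(kin$koff, 1 / 50e-9)
  # internal consistency: dG0 = RT log(koff / (kon C0)) of its own fields
  expect_equal(kin$dG0, 1.9872e-3 * 298 * log(kin$koff / kin$kon),
               tolerance = 1e-9)
  # koff/kon = 1 M implies dG0 = 0
  expect_equal(free_energy_from_rates(1e6, 1e6), 0)
  expect_error(rates_from_mfpt(-1, 50, 0.012), "positive")
})

test_that("measured rate pairs give the published free energies", {
  expect_equal(round(free_energy_from_rates(4.8e8, 7.5e5, 298), 1), -3.8)
  expect_equal(round(free_energy_from_rates(6.4e8, 1.3e6, 298), 1), -3.7)
})

test_that("binding frequency converts to an on-rate through the concentration", {
  expect_equal(signif(on_rate_from_frequency(0.01, 0.054), 3), 1.85e5)
  expect_equal(on_rate_from_frequency(1, 1), 1e6)
  expect_equal(signif(on_rate_from_frequency(0.02, 0.054), 3), 3.70e5)
  expect_error(on_rate_from_frequency(0.01, 0), "positive")
})

test_that("dissociation constants convert to standard free energies", {
  expect_equal(round(free_energy_from_kd(300e-6, 298), 1), -4.8)
  expect_equal(free_energy_from_kd(1, 298), 0)
  expect_equal(free_energy_from_kd(3.9e-3, 298), -3.28, tolerance = 0.005)
  expect_error(free_energy_from_kd(-1), "positive")
})

test_that("rates convert to characteristic times", {
  expect_equal(signif(timescale_from_rate(22) * 1e3, 2), 45)  # ms
  expect_equal(timescale_from_rate(1), 1)
  # pseudo-first-order binding time at 1 mM
  expect_equal(signif(timescale_from_rate(1.85e5 * 1e-3) * 1e3, 2), 5.4)
  expect_error(timescale_from_rate(0), "positive")
})

test_that("box metadata converts to molar concentrations", {
  expect_equal(concentration_from_box(1, 5.5356e-22), 3.0e-3, tolerance = 1e-4)
  expect_error(concentration_from_box(0, 1e-22), "integer >= 1")
  expect_equal(concentration_from_box(2, 2e-22),
               concentration_from_box(1, 1e-22))
})

test_that("free energies from rates agree with stationary populations", {
  # exact on the two-state benchmark: Kd from rates equals C_sim pi_u / pi_b
  sys <- msm_preset("twostate")
  conc <- concentration_from_box(1, sys$box_volume)
  m_on <- exact_mfpt(sys$rate_matrix, 1, 2)
  m_off <- exact_mfpt(sys$rate_matrix, 2, 1)
  kin <- rates_from_mfpt(m_on, m_off, conc)
  pi <- exact_stationary(sys$rate_matrix)
  dG_pop <- free_energy_from_kd(conc * pi[1] / pi[2])
  expect_equal(kin$dG0, dG_pop, tolerance = 1e-9)
  # within 0.1 kcal/mol when short-lived intermediates intervene
  sys5 <- msm_preset("binding5")
  conc5 <- concentration_from_box(1, sys5$box_volume)
  kin5 <- rates_from_mfpt(exact_mfpt(sys5$rate_matrix, 1, 5),
                          exact_mfpt(sys5$rate_matrix, 5, 1), conc5)
  pi5 <- exact_stationary(sys5$rate_matrix)
  dG_pop5 <- free_energy_from_kd(conc5 * (1 - pi5[5]) / pi5[5])
  expect_lt(abs(kin5$dG0 - dG_pop5), 0.1)
})

test_that("a deeper binding well lengthens residence, not the approach", {
  # ladder over the bound-state escape rate of the binding benchmark
  base <- unclass(msm_preset("binding5")$rate_matrix)
  mfpts <- lapply(c(0.1, 0.05, 0.02), function(k_out) {
    K <- base
    K[5, 4] <- k_out
    K[5, 5] <- 0
    K[5, 5] <- -sum(K[5, ])
    c(on = exact_mfpt(K, 1, 5), off = exact_mfpt(K, 5, 1))
  })
  off <- vapply(mfpts, `[[`, 1, "off")
  on <- vapply(mfpts, `[[`, 1, "on")
  expect_true(all(diff(off) > 0))
  expect_lt(max(abs(on - on[1])) / on[1], 0.02)
})
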