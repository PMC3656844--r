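# Phase reduction: response curves, synchronisation, locking.

Om20 <- 2 * pi / 20

test_that("the closed-form response curve has the pulse-map structure", {
  phi <- seq(0.01, 2 * pi - 0.01, length.out = 200)
  expect_equal(analytic_prc(phi, 0, Om20), rep(0, 200))
  # periodic, zero at mid-cycle, bimodal with sign-dependent stronger lobe
  g <- analytic_prc(phi, 1, Om20)
  expect_equal(analytic_prc(phi + 2 * pi, 1, Om20), g)
  expect_lt(abs(analytic_prc(pi, 1, Om20)), 1e-12)
  early <- max(g[phi < pi - 0.05]); late <- max(g[phi > pi + 0.05])
  expect_gt(early, 0.1); expect_gt(late, 0.1)   # two lobes
  expect_gt(late, early)                        # excitatory: late knee wins
  g_neg <- analytic_prc(phi, -1, Om20)
  expect_lt(max(g_neg), 0)                      # inhibition delays
  # the late-lobe dominance is a signature of excitation: it is absent
  # (the lobes balance) when the coupling sign flips
  skew_pos <- late - early
  skew_neg <- max(abs(g_neg[phi > pi + 0.05])) -
    max(abs(g_neg[phi < pi - 0.05]))
  expect_gt(skew_pos, 10 * abs(skew_neg))
})

test_that("simulated and closed-form response curves agree", {
  eta <- (Om20 / 2)^2
  np <- numerical_prc(eta, 0.3, phi = seq_len(16) / 17 * 2 * pi)
  expect_lt(max(abs(np$shift - analytic_prc(np$phi, 0.3, Om20))), 1e-2)
  # zero-strength pulse: no shift
  np0 <- numerical_prc(eta, 0, phi = c(1, 3, 5))
  expect_lt(max(abs(np0$shift)), 1e-9)
  expect_error(numerical_prc(-0.1, 0.3), "oscillating")
})

test_that("phase derivatives are uniform rotation plus PRC jumps", {
  net <- phase_network(c(Om20, Om20), matrix(c(0, 0.2, 0.4, 0), 2, 2))
  d <- phase_rhs(c(1, 2), net)
  expect_equal(d$drift, c(Om20, Om20))
  expect_equal(d$jump, c(0, 0))
  d2 <- phase_rhs(c(1, 2), net, spiking = 2L)
  expect_equal(d2$jump, c(analytic_prc(1, 0.4, Om20), 0))
  expect_error(phase_rhs(1, net), "dimension")
})

test_that("order parameter obeys its defining identities", {
  expect_equal(order_parameter(rep(1.3, 7))$r, 1)
  expect_lt(order_parameter(c(0.4, 0.4 + pi))$r, 1e-12)
  expect_lt(order_parameter(seq(0, 2 * pi, length.out = 9)[-9])$r, 1e-12)
})

test_that("event-driven simulation reproduces free-running periods", {
  net <- phase_network(rep(Om20, 2), matrix(0, 2, 2))
  sim <- simulate_phase_network(net, 200, init = c(0, 3))
  t1 <- sim$spikes$t[sim$spikes$neuron == 1]
  expect_equal(unique(round(diff(t1), 9)), 20)
})

test_that("synchronous-mode eigenvalue matches the dense deviation map", {
  for (n in c(3, 5, 10)) {
    for (s in c(0.02, -0.015)) {
      lam <- sync_mode_eigenvalue(s, 1, n)$lambda
      M <- sync_mode_matrix(s, 1, n)
      evs <- sort(eigen(M, only.values = TRUE)$values)
      # one neutral eigenvalue (global shift), the rest at the closed form
      expect_equal(sum(abs(evs - 1) < 1e-12), 1L)
      nontrivial <- evs[abs(evs - 1) > 1e-12]
      expect_equal(max(abs(nontrivial - lam)), 0, tolerance = 1e-12)
    }
  }
  expect_true(sync_mode_eigenvalue(0, 1, 5)$neutral)
})

test_that("positive coupling synchronises, negative disperses", {
  scan <- sync_stability_scan(c(-0.5, 0, 0.5))
  expect_false(scan$stable[1]); expect_gt(scan$lambda[1], 1)
  expect_equal(scan$lambda[2], 1)
  expect_true(scan$stable[3]); expect_lt(scan$lambda[3], 1)
  # short simulations move the order parameter the predicted way
  r_pos <- longrun_r(canonical_sync_network(0.5, n = 20), duration = 800)
  r_neg <- longrun_r(canonical_sync_network(-0.5, n = 20), duration = 800)
  expect_gt(r_pos, 0.95)
  expect_lt(r_neg, 0.2)
})

test_that("two-oscillator locking covers the three timing regimes", {
  # symmetric positive coupling: stable synchrony, unstable antiphase
  ls <- phase_locked_states(canonical_timing_network("synchrony"))
  expect_false(ls$degenerate)
  sync_row <- ls$states[which.min(pmin(ls$states$x, 2 * pi - ls$states$x)), ]
  expect_lt(min(sync_row$x, 2 * pi - sync_row$x), 0.05)
  expect_true(sync_row$stable)
  anti <- ls$states[which.min(abs(ls$states$x - pi)), ]
  expect_false(anti$stable)
  # strong asymmetry: no locked state (drifting relative phase)
  ls2 <- phase_locked_states(canonical_timing_network("drift"))
  expect_equal(nrow(ls2$states), 0L)
  # near the saddle-node: one weakly stable state and its separatrix
  ls3 <- phase_locked_states(canonical_timing_network("monostable"))
  expect_equal(sum(ls3$states$stable), 1L)
  expect_equal(sum(!ls3$states$stable), 1L)
  # zero coupling: every offset neutrally locked
  net0 <- phase_network(c(Om20, Om20), matrix(0, 2, 2))
  expect_true(phase_locked_states(net0)$degenerate)
})

test_that("locking verdicts agree with simulated relative-phase dynamics", {
  agree <- 0; total <- 0
  for (seed in 1:6) {
    k12 <- with_seed(seed, stats::runif(1, 0.01, 0.2))
    k21 <- with_seed(seed + 50, stats::runif(1, 0.01, 0.2))
    net <- phase_network(c(Om20, Om20),
                         matrix(c(0, k21, k12, 0), 2, 2))
    ls <- phase_locked_states(net)
    sim <- simulate_phase_coupled(net, 1500, init = c(0.3, 2.5), dt = 0.25)
    x_end <- (sim$phases[2, ncol(sim$phases)] -
                sim$phases[1, ncol(sim$phases)]) %% (2 * pi)
    stable_x <- ls$states$x[ls$states$stable]
    converged <- length(stable_x) > 0 &&
      min(abs(((x_end - stable_x + pi) %% (2 * pi)) - pi)) < 0.15
    predicted <- length(stable_x) > 0
    total <- total + 1
    if (converged == predicted) agree <- agree + 1
  }
  expect_gte(agree / total, 5 / 6)
})

test_that("relative spike timing series reports offsets modulo the period", {
  t1 <- seq(0, 200, by = 20)
  rs_sync <- relative_phase_series(t1, t1[-1])
  expect_lt(max(abs(rs_sync$rel)), 1e-12)
  rs_anti <- relative_phase_series(t1, t1[-length(t1)] + 10)
  expect_equal(unique(round(rs_anti$rel, 9)), 0.5)
  expect_equal(nrow(relative_phase_series(5, 10)), 0L)
})
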