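# Spiking core: closed-form period/rate, right-hand sides, integrator.

test_that("closed-form period matches numeric quadrature and its scaling", {
  for (eta in c(0.02, 0.25, 1, 4)) {
    expect_equal(closed_form_period(eta), quad_period(eta), tolerance = 1e-8)
  }
  # quadrupling the radicand halves the period
  expect_equal(closed_form_period(4 * 0.37),
               closed_form_period(0.37) / 2)
  # negative radicand: infinite period, zero rate
  expect_identical(closed_form_period(-0.5), Inf)
  expect_identical(firing_rate(-0.5), 0)
  expect_identical(firing_rate(0), 0)
})

test_that("rate is the reciprocal of the period and monotone in drive", {
  eta <- c(0.1, 0.5, 1, 2, 5)
  expect_equal(firing_rate(eta) * closed_form_period(eta), rep(1, 5))
  expect_true(all(diff(firing_rate(seq(0, 3, by = 0.1))) >= 0))
})

test_that("phase derivative: suprathreshold positivity, subthreshold rest,
          linear coupling", {
  p <- network_params(matrix(0, 1, 1))
  th <- seq(0, 2 * pi, length.out = 721)
  # constant suprathreshold drive: strictly positive over the whole cycle
  d_sup <- vapply(th, function(x) theta_rhs(x, 0, p, input = 0.3),
                  numeric(1))
  expect_true(all(d_sup > 0))
  # zero drive: the derivative vanishes somewhere (a resting state exists)
  d_sub <- vapply(th, function(x) theta_rhs(x, 0, p, input = 0),
                  numeric(1))
  expect_lt(min(d_sub), 1e-12)
  # the coupling contribution is linear in the weights
  C <- matrix(c(0.2, -0.4, 0.3, 0.1), 2, 2)
  p1 <- network_params(C); p2 <- network_params(2 * C)
  th2 <- c(1, 2.5); om <- c(0.7, 1.3)
  base <- theta_rhs(th2, rep(0, 2), p1, input = 0)
  contrib1 <- theta_rhs(th2, om, p1, input = 0) - base
  contrib2 <- theta_rhs(th2, om, p2, input = 0) - base
  expect_equal(contrib2, 2 * contrib1)
})

test_that("drive variable decays with tau_s and jumps by k at spikes", {
  p <- network_params(matrix(0, 2, 2), tau_s = 20, k = 0.5)
  d <- omega_rhs(c(1, 2), p)
  expect_equal(as.numeric(d), -c(1, 2) / 20)
  expect_equal(attr(d, "jump"), c(0, 0))
  d2 <- omega_rhs(c(1, 2), p, spikes_in_step = c(2L, 2L))
  expect_equal(attr(d2, "jump"), c(0, 1))   # two spikes of neuron 2
  # zero k: spikes leave the drive untouched
  p0 <- network_params(matrix(0, 2, 2), k = 0)
  expect_equal(attr(omega_rhs(c(1, 2), p0, spikes_in_step = 1L), "jump"),
               c(0, 0))
  # verified against simulation: a free-running neuron's drive relaxes at
  # tau_s between spikes
  p1 <- network_params(matrix(0, 1, 1), k = 0.5)
  sim <- simulate_network(p1, input = 1, init = list(theta = 0, omega = 2),
                          duration = 2, dt = 0.01)
  i0 <- sum(sim$spikes$t < 1e-9)
  expect_equal(sim$omega[1, sim$time == 1], 2 * exp(-1 / 20) + 0.5 * i0,
               tolerance = 1e-6)
})

test_that("simulated interspike intervals converge to the closed form", {
  eta <- 0.25
  T0 <- closed_form_period(eta)
  expect_lt(abs(sim_isi(eta, dt = 0.01) - T0) / T0, 1e-3)
  # convergence order at least one in dt
  e1 <- abs(sim_isi(eta, dt = 0.08) - T0)
  e2 <- abs(sim_isi(eta, dt = 0.04) - T0)
  expect_lt(e2, e1 / 1.8)
})

test_that("subthreshold drive produces no spikes", {
  p <- network_params(matrix(0, 1, 1))
  sim <- simulate_network(p, input = -0.1, init = list(theta = 0, omega = 0),
                          duration = 100, dt = 0.05)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("reruns with identical seed and schedule are bit-identical", {
  p <- network_params(two_node_matrix(-0.5, 0.3, 0.2, 0), k = 0.5)
  s1 <- simulate_network(p, input = c(0.5, 0.6), duration = 150, seed = 11)
  s2 <- simulate_network(p, input = c(0.5, 0.6), duration = 150, seed = 11)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$omega, s2$omega)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("identical uncoupled neurons fire with equal interspike
          intervals", {
  p <- network_params(matrix(0, 3, 3), k = 0.3)
  sim <- simulate_network(p, input = 0.8,
                          init = list(theta = rep(1, 3), omega = rep(0, 3)),
                          duration = 60, dt = 0.02)
  isis <- vapply(1:3, function(i) mean(interspike_intervals(sim, i)),
                 numeric(1))
  expect_lt(diff(range(isis)), 1e-8)
})

test_that("dimension mismatches raise structured errors", {
  p <- network_params(matrix(0, 2, 2))
  expect_error(theta_rhs(1, c(0, 0), p), "dimension")
  expect_error(omega_rhs(1, p), "dimension")
  expect_error(simulate_network(p, 0, init = list(theta = 1, omega = 1),
                                duration = 1), "init dimensions")
})
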