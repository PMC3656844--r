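# Independent oracles used across the suite.

# Period of the phase equation by numeric quadrature of dtheta / thetadot
# over one cycle (independent of the closed form under test).
quad_period <- function(eta) {
  stats::integrate(function(th) 1 / ((1 - cos(th)) + (1 + cos(th)) * eta),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

# Mean interspike interval of a single uncoupled neuron at constant drive.
sim_isi <- function(eta, dt, duration = 25 * closed_form_period(eta)) {
  p <- network_params(matrix(0, 1, 1), k = 0)
  sim <- simulate_network(p, input = eta,
                          init = list(theta = 0, omega = 0),
                          duration = duration, dt = dt)
  mean(interspike_intervals(sim))
}

# Long-run order parameter of a phase-coupled network.
longrun_r <- function(net, duration = 2000, seed = 3) {
  sim <- simulate_phase_coupled(net, duration, seed = seed, dt = 0.5,
                                record_dt = 10)
  tail_cols <- (ncol(sim$phases) - 10):ncol(sim$phases)
  mean(apply(sim$phases[, tail_cols, drop = FALSE], 2,
             function(p) order_parameter(p)$r))
}

expect_label <- function(report, label) {
  expect_equal(report$classification, label)
}
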