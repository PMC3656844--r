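# Multifunctional circuit and the subspace-similarity statistic.

test_that("subspace similarity satisfies its defining identities", {
  set.seed(2)
  E <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]
  expect_equal(subspace_similarity(E, E), 0)
  # two leading columns swapped: the formula scores exactly 4
  Eswap <- E[, c(2, 1, 3, 4)]
  expect_equal(subspace_similarity(E, Eswap), 4)
  # simultaneous ambient rotation leaves the score unchanged
  R <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  E2 <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]
  expect_equal(subspace_similarity(R %*% E, R %*% E2),
               subspace_similarity(E, E2), tolerance = 1e-10)
  expect_error(subspace_similarity(E * 2, E), "orthonormal")
})

test_that("gating schedules validate and evaluate with pulses", {
  seg <- data.frame(t0 = c(0, 100), t1 = c(100, 200),
                    level_1 = c(1, 0), level_2 = c(0, 1))
  pul <- data.frame(t = 150, duration = 10, mode = 1L, amplitude = 3)
  sch <- gating_schedule(seg, pul)
  expect_equal(schedule_levels(sch, 50), c(1, 0))
  expect_equal(schedule_levels(sch, 155), c(0 + 3, 1))
  expect_equal(schedule_levels(sch, 165), c(0, 1))
  bad <- data.frame(t0 = c(0, 120), t1 = c(100, 200),
                    level_1 = c(1, 0), level_2 = c(0, 1))
  expect_error(gating_schedule(bad), "contiguous")
})

test_that("the gated skeleton sub-networks realise the three flows", {
  S <- canonical_skeleton()$coupling
  for (fl in c("bistable", "limit-cycle", "monostable")) {
    sys <- rate_system(S, input = canonical_mode_levels(fl), k = 0.5)
    rep <- classify_flow(sys, box = c(0, 14), grid_n = 5)
    expect_label(rep, toupper(gsub("-", "_", fl)))
  }
})

test_that("a stationary surrogate yields a trendless similarity series", {
  set.seed(9)
  # white-noise channels with distinct variances, no structural change
  x <- matrix(rnorm(12 * 800), 12, 800) * seq(0.5, 2, length.out = 12)
  ss <- sliding_pca(x, window = 160, overlap = 100, n_components = 6)
  s <- ss$similarity[-1]
  half <- floor(length(s) / 2)
  expect_lt(abs(mean(s[1:half]) - mean(s[(half + 1):length(s)])),
            2 * stats::sd(s))
  # duplicated window content: similarity exactly zero
  xdup <- cbind(x[, 1:160], x[, 1:160], x[, 1:160])
  ssd <- sliding_pca(xdup, window = 160, overlap = 0, n_components = 6)
  expect_lt(ssd$similarity[2], 1e-20)
})

test_that("the sign convention removes the solver's arbitrary eigenvector
          signs", {
  set.seed(10)
  Ea <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:5]
  Eb <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:5]
  base <- subspace_similarity(fix_signs(Ea), fix_signs(Eb))
  for (i in 1:10) {
    Da <- diag(sample(c(-1, 1), 5, replace = TRUE))
    Db <- diag(sample(c(-1, 1), 5, replace = TRUE))
    expect_equal(subspace_similarity(fix_signs(Ea %*% Da),
                                     fix_signs(Eb %*% Db)),
                 base, tolerance = 1e-12)
  }
})

test_that("the multifunctional network is built with the documented
          heterogeneity", {
  net <- build_multifunctional()
  expect_equal(net$n, 25L)
  expect_equal(length(attr(net, "mode")), 25L)
  expect_equal(mean(net$k), 0.5, tolerance = 1e-12)
  expect_gt(stats::sd(net$k), 0)
})

test_that("a short gated run produces mode mean fields and currents", {
  net <- build_multifunctional()
  seg <- data.frame(t0 = 0, t1 = 150,
                    level_1 = 0.8, level_2 = -8, level_3 = -8,
                    level_4 = -8)
  sim <- run_schedule(net, gating_schedule(seg), seed = 4)
  expect_equal(dim(sim$mode_omega), c(4L, length(sim$time)))
  late <- sim$time > 100
  expect_gt(mean(sim$mode_omega[1, late]), 1)       # mode 1 driven
  expect_lt(max(sim$mode_omega[3, late]), 0.2)      # mode 3 silenced
  cur <- received_currents(sim)
  expect_equal(dim(cur), dim(sim$omega))
  # currents live in the coupling column space: rank at most 4
  sv <- svd(cur[, late])$d
  expect_lt(sv[5] / sv[1], 1e-8)
  # the first-component trace follows the dominant mode's mean field
  # (over a record whose variance is carried by that mode's activation)
  tr <- first_component_trace(sim$omega)
  m1 <- sim$mode_omega[1, ]
  expect_gt(abs(stats::cor(tr, m1)), 0.9)
})
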