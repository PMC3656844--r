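# Three-node reduction and the planar excitable reference system.

test_that("singular-vector projection separates normal and plane", {
  A <- decompose_symmetry(heteroclinic_matrix(1, 0.4))$A
  b <- svd_projection(A)
  expect_equal(b$normal, rep(1, 3) / sqrt(3), tolerance = 1e-12)
  expect_equal(crossprod(b$B), diag(3), tolerance = 1e-12)
  # projection plus reconstruction is exact
  v <- c(0.3, -1.2, 2.2)
  expect_equal(as.numeric(b$B %*% crossprod(b$B, v)), v)
  expect_error(svd_projection(matrix(0, 3, 3)), "zero")
  expect_error(svd_projection(heteroclinic_matrix(1, 0.4)), "antisymmetric")
})

basis03 <- svd_projection(decompose_symmetry(heteroclinic_matrix(1, 0.3))$A)

test_that("the reduced phase flow is periodic and driftless when
          symmetric", {
  m <- reduce_to_phase(canonical_three_node(0), basis = basis03)
  phis <- seq(0, 2 * pi, length.out = 128)
  expect_equal(m$flow(phis), m$flow(phis + 2 * pi), tolerance = 1e-10)
  expect_lt(abs(mean(m$flow(phis[-128]))), 1e-3)
  fp <- phase_fixed_points(m)
  expect_equal(length(fp$stable), 3L)
  expect_equal(length(fp$unstable), 3L)
})

test_that("reduced fixed points match the projected full-system states", {
  sys <- canonical_three_node(0.2)
  m <- reduce_to_phase(sys, basis = basis03)
  red <- sort(phase_fixed_points(m)$stable)
  full <- find_fixed_points(sys, box = c(0, 4))
  full <- full[full$stable, 1:3, drop = FALSE]
  ang <- sort(apply(full, 1, function(w) {
    atan2(sum(w * basis03$e2), sum(w * basis03$e1)) %% (2 * pi)
  }))
  expect_equal(length(red), length(ang))
  expect_lt(max(abs(red - ang)), 0.05)
})

test_that("zeros of the reduced flow agree with a dense sign scan", {
  m <- reduce_to_phase(canonical_three_node(0.15), basis = basis03)
  fp <- phase_fixed_points(m)
  grid <- seq(0, 2 * pi, length.out = 10001)
  v <- m$flow(grid)
  brackets <- which(v[-length(v)] * v[-1] < 0)
  expect_equal(length(fp$stable) + length(fp$unstable), length(brackets))
})

test_that("cyclic asymmetry drives a bifurcation to a phase limit cycle", {
  fam <- function(a) reduce_to_phase(canonical_three_node(a),
                                     basis = basis03)
  sc <- bifurcation_scan(fam, c(0, 1), tol = 1e-3, coarse_n = 11)
  expect_gt(sc$alpha_critical, 0)
  expect_lt(sc$alpha_critical, 1)
  # fixed-point count never increases along the scanned branch
  expect_true(all(diff(sc$scan$n_fixed) <= 0))
  # at full asymmetry the flow has no zeros: a rotation
  fp1 <- phase_fixed_points(fam(1))
  expect_equal(length(fp1$stable) + length(fp1$unstable), 0L)
  expect_true(all(fam(1)$flow(seq(0, 2 * pi, length.out = 64)) < 0) ||
                all(fam(1)$flow(seq(0, 2 * pi, length.out = 64)) > 0))
  # widening the range does not move the bifurcation point
  sc2 <- bifurcation_scan(fam, c(0, 1.4), tol = 1e-3, coarse_n = 15)
  expect_lt(abs(sc2$alpha_critical - sc$alpha_critical), 0.02)
})

test_that("the further asymmetry leaves one stable state with a nearby
          separatrix", {
  m <- reduce_to_phase(canonical_three_node(0.3, 0.6), basis = basis03)
  fp <- phase_fixed_points(m)
  expect_equal(length(fp$stable), 1L)
  expect_equal(length(fp$unstable), 1L)
  # full system: a single stable state probed by kicks rides a transient
  rep <- classify_flow(canonical_three_node(0.3, 0.6), box = c(0, 4))
  expect_equal(sum(rep$fixed_points$stable), 1L)
  expect_gt(rep$protocol$large$amplification, 1.8)
  expect_true(rep$protocol$large$returned)
})

test_that("reduced and full three-node systems share the bifurcation
          structure", {
  expect_label(classify_flow(canonical_three_node(0), box = c(0, 4)),
               "MULTISTABLE")
  expect_label(classify_flow(canonical_three_node(0.8), box = c(0, 4)),
               "LIMIT_CYCLE")
})

test_that("the planar excitable system realises its three regimes", {
  for (reg in c("monostable", "bistable", "limit-cycle")) {
    p <- excitator_params(reg)
    rep <- classify_flow(function(x) excitator_rhs(x, p), n = 2,
                         box = c(-3, 3), tau = 2)
    expect_label(rep, toupper(gsub("-", "_", reg)))
  }
  # nullcline intersections coincide with root-found fixed points
  p <- excitator_params("bistable")
  nl <- excitator_nullclines(p)
  fp <- find_fixed_points(f = function(x) excitator_rhs(x, p),
                          box = c(-3, 3), n = 2)
  expect_equal(nrow(fp), 3L)
  for (i in seq_len(nrow(fp))) {
    x <- fp$w1[i]; y <- fp$w2[i]
    expect_lt(abs(y - (x^3 / 3 - x - p$I)), 1e-6)       # on the x-nullcline
    expect_lt(abs(x - p$a + p$b * y), 1e-6)             # on the y-nullcline
  }
})
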