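# Firing-rate reduction: fixed points, mode analysis, nullclines,
# classification.

test_that("rate derivative has the required zeros and analytic Jacobian", {
  sys0 <- rate_system(matrix(0, 2, 2), input = 0, k = 0.5)
  expect_equal(rate_rhs(c(0, 0), sys0), c(0, 0))
  cz <- canonical_two_node("bistable")
  sys <- rate_system(cz$coupling, input = cz$input, k = cz$k)
  fp <- find_fixed_points(sys, box = c(0, 8))
  expect_gt(nrow(fp), 0)
  for (i in seq_len(nrow(fp))) {
    w <- as.numeric(fp[i, 1:2])
    expect_lt(sqrt(sum(rate_rhs(w, sys)^2)), 1e-9)
    expect_equal(rate_jacobian(w, sys),
                 numerical_jacobian(function(x) rate_rhs(x, sys), w),
                 tolerance = 1e-5)
  }
  expect_error(rate_rhs(1, sys), "dimension")
})

test_that("coherent-mode fixed point solves its nullcline equation and
          grows with coupling", {
  expect_equal(mode_fixed_point(0, 5, input = 0)$omega, 0)
  oms <- vapply(seq(0.02, 0.4, length.out = 8), function(cc) {
    fp <- mode_fixed_point(cc, 5, k = 0.5, input = 0.3)
    sys <- rate_system(matrix(cc, 5, 5), input = 0.3, k = 0.5)
    expect_lt(max(abs(rate_rhs(rep(fp$omega, 5), sys))), 1e-10)
    fp$omega
  }, numeric(1))
  expect_true(all(diff(oms) > 0))
})

test_that("closed-form mode eigenvalues match the numerical Jacobian over a
          coupling grid", {
  grid <- seq(-0.3, 0.5, length.out = 21)
  for (cc in grid) {
    fp <- mode_fixed_point(cc, 5, k = 0.5, input = 0.3)
    ev <- mode_eigenvalue(cc, 5, k = 0.5, input = 0.3)
    sys <- rate_system(matrix(cc, 5, 5), input = 0.3, k = 0.5)
    evs <- sort(Re(eigen(numerical_jacobian(
      function(w) rate_rhs(w, sys), rep(fp$omega, 5)),
      only.values = TRUE)$values))
    expect_lt(abs(ev$unique - evs[which.max(abs(evs - ev$degenerate))]),
              1e-6)
    # the other n - 1 eigenvalues sit at the degenerate value
    others <- sort(abs(evs - ev$degenerate))[1:4]
    expect_lt(max(others), 1e-6)
  }
})

test_that("input dispersion is compressed by homogeneous positive
          coupling", {
  set.seed(7)
  I <- rnorm(10, 1, 0.3)
  disp <- vapply(c(0, 0.15, 0.3), function(cc) {
    sys <- rate_system(matrix(cc / 10, 10, 10), input = I, k = 0.5)
    tr <- simulate_rate(sys, rep(1, 10), 600, 2)
    stats::sd(tr[nrow(tr), -1])
  }, numeric(1))
  expect_true(all(diff(disp) < 0))
})

test_that("nullcline intersections coincide with fixed points", {
  cz <- canonical_two_node("fixed-point")
  sys <- rate_system(cz$coupling, input = cz$input, k = cz$k)
  nc <- nullclines(sys, box = c(0, 8), resolution = 161)
  fp <- find_fixed_points(sys, box = c(0, 8))
  expect_equal(nrow(fp), 1L)   # single intersection in the quadrant
  # the fixed point lies on both sampled curves (to grid tolerance)
  for (curve in c(nc$nc1, nc$nc2)) {
    dmin <- min(sqrt((curve$w1 - fp$w1[1])^2 + (curve$w2 - fp$w2[1])^2))
    expect_lt(dmin, 0.15)
  }
  # exchange symmetry: the two nullclines are mirror images
  m1 <- do.call(rbind, nc$nc1); m2 <- do.call(rbind, nc$nc2)
  for (r in c(10, 50, 100)) {
    p <- m1[r, ]
    expect_lt(min(abs(m2$w1 - p$w2) + abs(m2$w2 - p$w1)), 0.1)
  }
})

test_that("polynomial nullcline fits keep the intersection count", {
  # fits restricted to the interior window (rectified branches along the
  # axes are not graphs and are cropped away)
  win <- list(w1 = c(0.15, 7), w2 = c(0.15, 7))
  for (kind in c("fixed-point", "bistable", "limit-cycle", "monostable")) {
    cz <- canonical_two_node(kind)
    sys <- rate_system(cz$coupling, input = cz$input, k = cz$k)
    nc <- nullclines(sys, box = c(0, 8), resolution = 161)
    fit <- fit_polynomial_nullclines(nc, degree = 5, window = win)
    n_src <- count_intersections(sys, window = win)
    n_fit <- count_intersections(fit = fit)
    expect_equal(n_fit, n_src)
  }
  # residual decreases with degree on fixed samples
  cz <- canonical_two_node("bistable")
  sys <- rate_system(cz$coupling, input = cz$input, k = cz$k)
  nc <- nullclines(sys, box = c(0, 8), resolution = 121)
  xy <- do.call(rbind, nc$nc1)
  res <- vapply(c(2, 4, 6, 8), function(dg) {
    co <- fit_polynomial_nullclines(nc, degree = dg)$p1
    sum((xy$w2 - vapply(xy$w1, function(x) {
      sum(co * x^(seq_along(co) - 1))
    }, numeric(1)))^2)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8))
})

test_that("mean-rate approximation error behaves as expected", {
  expect_equal(reduction_error(1:5, 1:5), -745)
  # surrogate drive under equal-ISI and Poisson trains is computable from
  # the same rate; relative to the drive's own scale, the mean-rate flow
  # tracks high-rate trains better than low-rate ones (the per-spike jump
  # is a smaller fraction of the running level)
  r_hi <- 0.25; r_lo <- 0.02
  dur <- 1500
  e <- sapply(c(r_lo, r_hi), function(r) {
    lev <- r * 0.5 * 20                        # asymptotic drive level
    base <- surrogate_drive(r, dur, kind = "mean-rate") / lev
    iso <- surrogate_drive(r, dur, kind = "equal-isi") / lev
    poi <- surrogate_drive(r, dur, kind = "poisson", seed = 4) / lev
    c(isi = reduction_error(base, iso), poisson = reduction_error(base, poi))
  })
  expect_lt(e["isi", 2], e["isi", 1])
  expect_lt(e["poisson", 2], e["poisson", 1])
})

test_that("the four canonical two-node systems classify as the four flow
          classes", {
  for (kind in c("fixed-point", "limit-cycle")) {
    cz <- canonical_two_node(kind)
    rep <- classify_flow(rate_system(cz$coupling, input = cz$input,
                                     k = cz$k), box = c(0, 8))
    expect_label(rep, cz$label)
  }
})
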