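# Connectivity constructors and symmetry decomposition.

test_that("symmetric/antisymmetric decomposition is exact and idempotent", {
  sym <- matrix(c(0, 1, 1, 0), 2, 2)
  d <- decompose_symmetry(sym)
  expect_equal(d$S, sym)
  expect_equal(d$A, matrix(0, 2, 2))
  anti <- matrix(c(0, -1, 1, 0), 2, 2)
  d2 <- decompose_symmetry(anti)
  expect_equal(d2$S, matrix(0, 2, 2))
  expect_equal(d2$A, anti)
  set.seed(5)
  M <- matrix(rnorm(25), 5, 5)
  d3 <- decompose_symmetry(M)
  expect_equal(d3$S + d3$A, M)
  expect_equal(d3$S, t(d3$S))
  expect_equal(d3$A, -t(d3$A))
  # projections are idempotent
  expect_equal(decompose_symmetry(d3$S)$S, d3$S)
  expect_equal(decompose_symmetry(d3$A)$A, d3$A)
  expect_error(decompose_symmetry(matrix(0, 2, 3)), "square")
})

test_that("two-node parameterisation round-trips exactly", {
  expect_equal(two_node_matrix(0.7, 0.2, 0, 0),
               t(two_node_matrix(0.7, 0.2, 0, 0)))  # a = d = 0 => symmetric
  set.seed(8)
  for (i in 1:10) {
    p <- as.list(rnorm(4)); names(p) <- c("s", "c", "a", "d")
    C <- do.call(two_node_matrix, p)
    expect_equal(decompose_two_node(C), p)
  }
  # the canonical sets decompose back to their stored parameters
  for (kind in c("fixed-point", "limit-cycle", "bistable", "monostable")) {
    cz <- canonical_two_node(kind)
    expect_equal(decompose_two_node(cz$coupling), cz$decomposition)
  }
})

test_that("cyclic three-node family has circulant antisymmetric part", {
  expect_equal(decompose_symmetry(heteroclinic_matrix(1, 0))$A,
               matrix(0, 3, 3))
  A <- decompose_symmetry(heteroclinic_matrix(1, 0.4))$A
  # cyclic pattern: +alpha on the forward ring, -alpha backward
  cyc <- matrix(0, 3, 3)
  cyc[rbind(c(2, 1), c(3, 2), c(1, 3))] <- 0.4
  expect_equal(A, cyc - t(cyc))
  # further asymmetry: reduces at beta = 0, differs from the cyclic
  # pattern otherwise
  expect_equal(further_asymmetry_matrix(1, 0.3, 0),
               heteroclinic_matrix(1, 0.3))
  A2 <- decompose_symmetry(further_asymmetry_matrix(1, 0.3, 0.5))$A
  expect_gt(max(abs(A2 - A2[2, 1] * (cyc - t(cyc)) / 0.4)), 0.1)
})

test_that("skeleton expansion preserves the mode-level mean field", {
  skel <- canonical_skeleton()
  C <- expand_skeleton(skel)
  modes <- attr(C, "mode")
  expect_equal(dim(C), c(25L, 25L))
  expect_equal(as.integer(table(modes)), skel$counts)
  # identical within-mode states: expanded derivative equals the
  # skeleton-level derivative, exactly
  w4 <- c(1.2, 0.4, 2.0, 0.7)
  inp4 <- c(0.5, 0.5, -1, 0.2)
  sys25 <- rate_system(unclass(C), input = inp4[modes], k = 0.5)
  sys4 <- rate_system(skel$coupling, input = inp4, k = 0.5)
  expect_equal(rate_rhs(w4[modes], sys25), rate_rhs(w4, sys4)[modes])
  # a symmetric skeleton expands to a symmetric matrix (equal counts)
  S <- matrix(c(0, -1, -1, 0), 2, 2)
  Ce <- expand_skeleton(mode_skeleton(S, c(4L, 4L)))
  expect_equal(unclass(Ce), t(unclass(Ce)), ignore_attr = TRUE)
})

test_that("neuron counts split evenly with leading remainder", {
  expect_equal(split_counts(25, 4), c(7L, 6L, 6L, 6L))
  expect_equal(sum(split_counts(23, 5)), 23L)
})

test_that("coupling matrices round-trip through text files", {
  path <- tempfile(fileext = ".txt")
  C <- heteroclinic_matrix(1, 0.3)
  write_coupling(C, path)
  expect_equal(unname(read_coupling(path)), C)
  # byte-stable on rewrite
  path2 <- tempfile(fileext = ".txt")
  write_coupling(read_coupling(path), path2)
  expect_identical(readLines(path), readLines(path2))
})
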