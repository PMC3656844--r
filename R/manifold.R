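# Reduction of the three-node rate network to a single phase variable.
#
# The antisymmetric component of the coupling picks out a preferred plane:
# its right singular vectors split state space into a normal direction
# (the zero singular direction, proportional to (1,1,1) for the cyclic
# family) and two in-plane directions.  Writing the in-plane components in
# polar coordinates and replacing radius and normal coordinate by their
# phase averages leaves a scalar 2*pi-periodic flow dphi/dt whose zeros are
# the fixed points of the slow dynamics on the manifold.

#' Projection basis from the asymmetry matrix
#'
#' Right singular vectors of the antisymmetric part of a 3x3 coupling
#' matrix, ordered as (in-plane 1, in-plane 2, normal); the normal is the
#' singular vector of the (numerically) zero singular value.  Signs are
#' fixed by making the first nonzero component of each vector positive.
#'
#' @param A antisymmetric 3x3 matrix (checked to `tol`).
#' @param tol asymmetry/zero tolerance.
#' @return object of class `projection_basis`: list with unit vectors `e1`,
#'   `e2`, `normal` and the full matrix `B = cbind(e1, e2, normal)`.
#' @export
svd_projection <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == 3, ncol(A) == 3)
  if (max(abs(A + t(A))) > tol * max(1, max(abs(A)))) {
    stop("input must be antisymmetric", call. = FALSE)
  }
  if (max(abs(A)) < tol) {
    stop("zero asymmetry matrix: no preferred plane", call. = FALSE)
  }
  sv <- svd(A)
  fix_sign <- function(v) {
    i <- which(abs(v) > 1e-12)[1]
    if (v[i] < 0) -v else v
  }
  e1 <- fix_sign(sv$v[, 1])
  e2 <- fix_sign(sv$v[, 2])
  nrm <- fix_sign(sv$v[, 3])
  # re-orthogonalise e2 against e1 (svd already orthogonal; sign fixes
  # cannot break orthogonality, this is belt and braces for degenerate
  # singular values)
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  structure(list(e1 = e1, e2 = e2, normal = nrm,
                 B = unname(cbind(e1, e2, nrm))),
            class = "projection_basis")
}

#' Reduce a simplified three-node rate system to a phase flow
#'
#' Transforms the vector field into the basis of [svd_projection()],
#' expresses the in-plane components in polar coordinates and determines
#' the self-consistent phase-averaged radius and normal coordinate
#' (the pair at which the phase averages of the radial and normal
#' velocities vanish), then returns the scalar phase flow evaluated on that
#' averaged ring.
#'
#' @param system a 3-node [rate_system()] (conventionally the simplified
#'   variant).
#' @param basis a `projection_basis`; by default computed from the
#'   antisymmetric part of `system$coupling` (for the symmetric case pass a
#'   basis, e.g. the one of a nearby asymmetric member of the family).
#' @param n_avg number of phase samples for the averages (default 512).
#' @param init optional starting values `c(rho, z)` for the averaged radius
#'   and normal coordinate; by default seeded from a short simulation.
#' @return object of class `reduced_phase_model`: list with `flow`
#'   (function phi -> dphi/dt, vectorised), `rho`, `z`, `basis`, `system`.
#' @export
reduce_to_phase <- function(system, basis = NULL, n_avg = 512, init = NULL) {
  stopifnot(inherits(system, "rate_system"), system$n == 3)
  if (is.null(basis)) {
    basis <- svd_projection(decompose_symmetry(system$coupling)$A)
  }
  B <- basis$B
  f <- function(w) rate_rhs(w, system)
  phis <- seq(0, 2 * pi, length.out = n_avg + 1)[-(n_avg + 1)]

  # velocities in (rho, phi, z) at a given ring
  polar_rates <- function(rho, z, phi) {
    xy <- cbind(rho * cos(phi), rho * sin(phi))
    W <- xy %*% t(B[, 1:2]) + matrix(z * B[, 3], length(phi), 3, byrow = TRUE)
    V <- t(apply(W, 1, f))
    vx <- V %*% B[, 1]; vy <- V %*% B[, 2]; vz <- V %*% B[, 3]
    cph <- cos(phi); sph <- sin(phi)
    list(rho = as.numeric(vx * cph + vy * sph),
         phi = as.numeric((vy * cph - vx * sph) / rho),
         z = as.numeric(vz))
  }

  if (is.null(init)) {
    # seed the averaged ring from the settled part of a trajectory
    tr <- simulate_rate(system, rep(0.5, 3) + c(0.3, 0, 0), 800, 2)
    w_end <- colMeans(tr[tr[, 1] > 400, -1, drop = FALSE])
    z0 <- sum(w_end * B[, 3])
    rho0 <- sqrt(max(sum(w_end^2) - z0^2, 0.05))
    init <- c(max(rho0, 0.1), z0)
  }

  avg_resid <- function(p) {
    pr <- polar_rates(p[1], p[2], phis)
    c(mean(pr$rho), mean(pr$z))
  }
  p <- init
  ok <- FALSE
  for (it in 1:80) {
    r <- avg_resid(p)
    if (sqrt(sum(r^2)) < 1e-10) { ok <- TRUE; break }
    J <- numerical_jacobian(avg_resid, p, h = 1e-6)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    sn <- sqrt(sum(step^2))
    if (sn > 0.5) step <- step * 0.5 / sn
    p <- p + step
    if (p[1] < 1e-3) p[1] <- 1e-3
  }
  if (!ok && sqrt(sum(avg_resid(p)^2)) > 1e-6) {
    stop("phase averaging failed to converge: residual ",
         signif(sqrt(sum(avg_resid(p)^2)), 3), call. = FALSE)
  }
  rho_bar <- p[1]; z_bar <- p[2]
  flow <- function(phi) polar_rates(rho_bar, z_bar, phi %% (2 * pi))$phi
  structure(list(flow = flow, rho = rho_bar, z = z_bar, basis = basis,
                 system = system),
            class = "reduced_phase_model")
}

#' @export
print.reduced_phase_model <- function(x, ...) {
  cat("<reduced_phase_model> rho =", signif(x$rho, 4),
      "z =", signif(x$z, 4), "\n")
  invisible(x)
}

#' Fixed points of a reduced phase flow
#'
#' All zeros of `dphi/dt` on `[0, 2*pi)` by sign-change bracketing on a
#' dense grid followed by bisection; stability from the slope sign.
#'
#' @param model a `reduced_phase_model` (or any list with a vectorised
#'   `flow` function).
#' @param grid_n number of grid points (default 2048).
#' @return list with numeric vectors `stable` and `unstable` (phases in
#'   radians), possibly empty.
#' @export
phase_fixed_points <- function(model, grid_n = 2048) {
  flow <- model$flow
  phi <- seq(0, 2 * pi, length.out = grid_n + 1)
  v <- flow(phi)
  zeros <- numeric(0); slopes <- numeric(0)
  for (i in seq_len(grid_n)) {
    if (v[i] == 0) {
      zeros <- c(zeros, phi[i])
      h <- 2 * pi / grid_n / 10
      slopes <- c(slopes, (flow(phi[i] + h) - flow(phi[i] - h)) / (2 * h))
    } else if (v[i] * v[i + 1] < 0) {
      root <- stats::uniroot(function(x) flow(x), c(phi[i], phi[i + 1]),
                             tol = 1e-12)$root
      zeros <- c(zeros, root %% (2 * pi))
      h <- 2 * pi / grid_n / 10
      slopes <- c(slopes, (flow(root + h) - flow(root - h)) / (2 * h))
    }
  }
  list(stable = zeros[slopes < 0], unstable = zeros[slopes >= 0])
}

#' Critical asymmetry of a phase-flow family
#'
#' Scans a one-parameter family of reduced phase models for the smallest
#' parameter value at which the flow loses all fixed points (the
#' bifurcation from multistability to a phase limit cycle), locating the
#' transition by bisection.
#'
#' @param family function `alpha -> reduced_phase_model` (or any object
#'   accepted by [phase_fixed_points()]).
#' @param range numeric `c(lo, hi)` parameter range, ordered.
#' @param tol bisection tolerance on the parameter (default 1e-4).
#' @param coarse_n coarse-scan resolution used to bracket the transition.
#' @return list with `alpha_critical` (or `NA` if no transition in range)
#'   and the coarse scan table (`alpha`, `n_fixed`).
#' @export
bifurcation_scan <- function(family, range = c(0, 1), tol = 1e-4,
                             coarse_n = 11) {
  if (range[2] <= range[1]) stop("range must be ordered", call. = FALSE)
  nfp <- function(alpha) {
    fp <- phase_fixed_points(family(alpha))
    length(fp$stable) + length(fp$unstable)
  }
  alphas <- seq(range[1], range[2], length.out = coarse_n)
  counts <- vapply(alphas, nfp, numeric(1))
  has <- counts > 0
  if (all(has) || !has[1]) {
    return(list(alpha_critical = NA_real_,
                scan = data.frame(alpha = alphas, n_fixed = counts)))
  }
  i <- which(!has)[1]
  lo <- alphas[i - 1]; hi <- alphas[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nfp(mid) > 0) lo <- mid else hi <- mid
  }
  list(alpha_critical = (lo + hi) / 2,
       scan = data.frame(alpha = alphas, n_fixed = counts))
}

# ---------------------------------------------------------------------------
# Reference two-dimensional excitable system
# ---------------------------------------------------------------------------

#' Planar excitable reference system
#'
#' A two-dimensional system of the excitable (FitzHugh-Nagumo) class used
#' as the behavioural reference for the flow repertoire: position `x` with
#' cubic local dynamics and velocity-like recovery variable `y`,
#' \deqn{\dot x = \tau_e (x + y - x^3/3 + I), \quad
#'       \dot y = -(x - a + b y)/\tau_e.}
#' Depending on `(a, b, I)` the system is monostable (one stable fixed
#' point with a nearby separatrix: suprathreshold kicks ride a large
#' excursion), bistable, or oscillates on a limit cycle.
#'
#' @param state numeric `c(x, y)`.
#' @param params list with `a`, `b`, `I`, `tau_e` (see
#'   [excitator_params()]).
#' @return derivative `c(dx, dy)`.
#' @export
excitator_rhs <- function(state, params) {
  x <- state[1]; y <- state[2]
  c(params$tau_e * (x + y - x^3 / 3 + params$I),
    -(x - params$a + params$b * y) / params$tau_e)
}

#' @rdname excitator_rhs
#' @param regime one of `"monostable"`, `"bistable"`, `"limit-cycle"`.
#' @return for `excitator_params`: parameter list for the chosen regime.
#' @export
excitator_params <- function(regime = c("monostable", "bistable",
                                        "limit-cycle")) {
  regime <- match.arg(regime)
  switch(regime,
    "monostable"  = list(a = 1.3, b = 0, I = 0, tau_e = 3),
    "bistable"    = list(a = 0, b = 2, I = 0, tau_e = 3),
    "limit-cycle" = list(a = 0.5, b = 0, I = 0, tau_e = 3))
}

#' Nullclines of the excitable reference system
#' @param params parameter list.
#' @param xlim range of `x`.
#' @param n samples.
#' @return list of two data frames (`x`, `y`), one per nullcline.
#' @export
excitator_nullclines <- function(params, xlim = c(-2.5, 2.5), n = 401) {
  x <- seq(xlim[1], xlim[2], length.out = n)
  ynull <- if (params$b == 0) {
    data.frame(x = rep(params$a, n), y = seq(-3, 3, length.out = n))
  } else {
    data.frame(x = x, y = (params$a - x) / params$b)
  }
  list(xnull = data.frame(x = x, y = x^3 / 3 - x - params$I), ynull = ynull)
}
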