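# Firing-rate reduction of the spiking network.
#
# Assuming the synaptic-drive variables evolve much more slowly than the
# phases, each neuron's spike train in the drive equation is replaced by
# its mean firing rate r = sqrt(max(0, drive))/pi, giving the closed rate
# system
#
#   d omega_i / dt = -omega_i/tau_s + (k/pi) sqrt(max(0, I_i + sum_j c_ij omega_j))
#
# The "simplified" variant drops the square root (keeping the rectification
# at zero) and absorbs the gain, leaving
#
#   d omega_i / dt = (-omega_i + max(0, I_i + sum_j c_ij omega_j)) / tau_s
#
# which in the relevant parameter regime produces the same qualitative
# flows and is the form used for the three-node phase reduction.

#' Rate-reduced network system
#'
#' @param coupling square coupling matrix (row = postsynaptic).
#' @param input per-neuron constant drive (recycled if scalar).
#' @param k spike-effect strength of the underlying spiking model.
#' @param tau_s synaptic timescale (ms).
#' @param simplified logical; drop the square root of the rate map (the
#'   rectification at zero drive is kept).
#' @return object of class `rate_system`.
#' @export
rate_system <- function(coupling, input = 0, k = K_DEFAULT, tau_s = 20,
                        simplified = FALSE) {
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != ncol(coupling)) stop("coupling must be square",
                                             call. = FALSE)
  n <- nrow(coupling)
  structure(
    list(n = n, coupling = coupling, input = rep_len(input, n), k = k,
         tau_s = tau_s, simplified = isTRUE(simplified)),
    class = "rate_system"
  )
}

#' @export
print.rate_system <- function(x, ...) {
  cat("<rate_system> n =", x$n, if (x$simplified) "(simplified)" else "",
      "| k =", x$k, "| tau_s =", x$tau_s, "\n")
  invisible(x)
}

#' Derivative of the rate system
#'
#' @param omega numeric state vector (same length as the system dimension).
#' @param system a [rate_system()].
#' @return derivative vector.
#' @export
rate_rhs <- function(omega, system) {
  stopifnot(inherits(system, "rate_system"))
  if (length(omega) != system$n) {
    stop("state dimension does not match system$n = ", system$n,
         call. = FALSE)
  }
  drive <- pmax(system$input + as.vector(system$coupling %*% omega), 0)
  if (system$simplified) {
    (-omega + drive) / system$tau_s
  } else {
    -omega / system$tau_s + (system$k / pi) * sqrt(drive)
  }
}

#' Integrate the rate system
#'
#' Thin wrapper over [deSolve::ode()] (fixed-step classical Runge-Kutta;
#' the rectified rate map is only piecewise smooth, so a fixed-step method
#' is used rather than a stiff solver with step-size control).
#'
#' @param system a [rate_system()].
#' @param init initial state vector.
#' @param duration total time (ms).
#' @param dt output/integration step (ms).
#' @return matrix: first column time, remaining columns the state.
#' @export
simulate_rate <- function(system, init, duration, dt = 0.5) {
  times <- seq(0, duration, by = dt)
  f <- function(t, y, p) list(rate_rhs(y, system))
  unname(deSolve::ode(y = as.numeric(init), times = times, func = f,
                      parms = NULL, method = "rk4"))
}

#' Mode fixed point under homogeneous coupling
#'
#' With all couplings equal (`coupling`, including self-coupling) and a
#' common constant input, every node obeys the same nullcline equation and
#' the coherent mode satisfies
#' \eqn{\omega^* = g\sqrt{n c\, \omega^* + I}}, \eqn{g = k\tau_s/\pi},
#' whose positive solution is returned (the quadratic's other root is
#' discarded).  When no positive solution exists the silent state
#' \eqn{\omega^* = 0} is reported with `exists = FALSE`.
#'
#' @param coupling common coupling value `c` (scalar).
#' @param n number of nodes.
#' @param k,tau_s model constants.
#' @param input common constant input (default 0).
#' @return list with `omega` (the fixed-point value) and `exists` (logical:
#'   a positive coherent mode exists).
#' @export
mode_fixed_point <- function(coupling, n, k = K_DEFAULT, tau_s = 20,
                             input = 0) {
  g <- k * tau_s / pi
  b <- n * coupling
  disc <- g^4 * b^2 + 4 * g^2 * input
  if (disc < 0) return(list(omega = 0, exists = FALSE))
  omega <- (g^2 * b + sqrt(disc)) / 2
  if (omega <= 0) {
    # no positive coherent mode; the silent state is the attractor
    return(list(omega = 0, exists = FALSE))
  }
  # consistency: the drive at the fixed point must be nonnegative
  if (b * omega + input < 0) return(list(omega = 0, exists = FALSE))
  list(omega = omega, exists = TRUE)
}

#' Eigenvalues of the rate Jacobian at the coherent mode
#'
#' At the homogeneous fixed point the Jacobian is the sum of a diagonal
#' relaxation and a rank-one coupling term, so its spectrum consists of
#' `n - 1` degenerate eigenvalues equal to `-1/tau_s` and a single unique
#' eigenvalue
#' \eqn{\lambda = -1/\tau_s + k n c / (2\pi\sqrt{D})},
#' \eqn{D = n c\,\omega^* + I}, which determines the stability of the mode
#' amplitude.  On the silent branch all eigenvalues are `-1/tau_s`.
#'
#' @inheritParams mode_fixed_point
#' @return list with `unique` (the distinguished eigenvalue) and
#'   `degenerate` (the `n - 1`-fold eigenvalue, `-1/tau_s`).
#' @export
mode_eigenvalue <- function(coupling, n, k = K_DEFAULT, tau_s = 20,
                            input = 0) {
  fp <- mode_fixed_point(coupling, n, k, tau_s, input)
  if (!fp$exists || (n * coupling * fp$omega + input) <= 0) {
    return(list(unique = -1 / tau_s, degenerate = -1 / tau_s))
  }
  D <- n * coupling * fp$omega + input
  list(unique = -1 / tau_s + k * n * coupling / (2 * pi * sqrt(D)),
       degenerate = -1 / tau_s)
}

#' Analytic Jacobian of the rate system
#'
#' @param omega state vector.
#' @param system a [rate_system()].
#' @return Jacobian matrix of [rate_rhs()] at `omega` (one-sided convention
#'   at the rectification kink: silent units contribute zero gain).
#' @export
rate_jacobian <- function(omega, system) {
  drive <- system$input + as.vector(system$coupling %*% omega)
  if (system$simplified) {
    gain <- as.numeric(drive > 0)
    (-diag(system$n) + gain * system$coupling) / system$tau_s
  } else {
    gain <- ifelse(drive > 0, system$k / (2 * pi * sqrt(pmax(drive, 1e-300))),
                   0)
    -diag(system$n) / system$tau_s + gain * system$coupling
  }
}

#' Numerical Jacobian of a vector field
#'
#' Central finite differences; used as the independent check of the
#' closed-form mode eigenvalues and for linear stability of fixed points.
#'
#' @param f function of the state vector returning the derivative vector.
#' @param x state at which to differentiate.
#' @param h step (default `1e-6` scaled by state magnitude).
#' @return Jacobian matrix.
#' @export
numerical_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (j in seq_len(n)) {
    hj <- if (is.null(h)) 1e-6 * max(1, abs(x[j])) else h
    e <- numeric(n); e[j] <- hj
    J[, j] <- (f(x + e) - f(x - e)) / (2 * hj)
  }
  J
}

# ---------------------------------------------------------------------------
# Fixed points, nullclines, classification
# ---------------------------------------------------------------------------

#' Locate fixed points of the rate system
#'
#' Damped Newton iterations started from a dense grid of initial
#' conditions, followed by deduplication.  Stability is assessed from the
#' eigenvalues of the numerical Jacobian.
#'
#' @param system a [rate_system()] (or any object for which [rate_rhs()]
#'   applies via `f`).
#' @param box numeric vector `c(lo, hi)` bounding each coordinate of the
#'   search region.
#' @param grid_n grid points per axis (default 20).
#' @param tol residual tolerance for accepting a root.
#' @param dedup_tol distance below which two roots are considered equal.
#' @param f optional vector field to use instead of `rate_rhs(., system)`.
#' @param n state dimension when `f` is given (inferred by probing when
#'   omitted).
#' @return data frame with fixed-point coordinates (`w1`, `w2`, ...),
#'   `stable` (logical) and `max_re` (largest real part of the Jacobian
#'   spectrum).
#' @export
find_fixed_points <- function(system = NULL, box = c(0, 10), grid_n = NULL,
                              tol = 1e-9, dedup_tol = 1e-6, f = NULL,
                              n = NULL) {
  if (is.null(f)) {
    stopifnot(inherits(system, "rate_system"))
    f <- function(x) rate_rhs(x, system)
    jac <- function(x) rate_jacobian(x, system)
    n <- system$n
  } else {
    if (is.null(n)) n <- lengths_from_f(f, box)
    jac <- function(x) numerical_jacobian(f, x)
  }
  # keep the total number of Newton starts manageable in dimension > 2
  if (is.null(grid_n)) grid_n <- max(5L, round(400^(1 / n)))
  axis <- seq(box[1], box[2], length.out = grid_n)
  grid <- as.matrix(do.call(expand.grid, rep(list(axis), n)))
  roots <- list()
  span <- box[2] - box[1]
  for (r in seq_len(nrow(grid))) {
    x <- grid[r, ]
    ok <- FALSE
    for (it in 1:40) {
      fx <- f(x)
      if (any(!is.finite(fx))) break
      if (sqrt(sum(fx^2)) < tol) { ok <- TRUE; break }
      J <- jac(x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      # damping: keep steps bounded to stay in the basin
      sn <- sqrt(sum(step^2))
      if (sn > span / 2) step <- step * (span / 2) / sn
      x_new <- x + step
      x <- x_new
      if (any(!is.finite(x)) || any(x < box[1] - span) ||
          any(x > box[2] + span)) break
    }
    if (ok && all(x >= box[1] - 1e-8) && all(x <= box[2] + 1e-8)) {
      roots[[length(roots) + 1]] <- x
    }
  }
  if (!length(roots)) {
    out <- as.data.frame(matrix(numeric(0), 0, n))
    names(out) <- paste0("w", seq_len(n))
    out$stable <- logical(0); out$max_re <- numeric(0)
    return(out)
  }
  pts <- unique_points(do.call(rbind, roots), dedup_tol)
  stab <- apply(pts, 1, function(x) {
    ev <- eigen(numerical_jacobian(f, x), only.values = TRUE)$values
    max(Re(ev))
  })
  out <- as.data.frame(pts)
  names(out) <- paste0("w", seq_len(n))
  out$stable <- stab < 0
  out$max_re <- stab
  out
}

lengths_from_f <- function(f, box) {
  for (n in 1:6) {
    ok <- tryCatch({
      out <- f(rep(mean(box), n))
      length(out) == n && all(is.finite(out))
    }, error = function(e) FALSE)
    if (ok) return(n)
  }
  stop("could not infer state dimension", call. = FALSE)
}

unique_points <- function(pts, tol) {
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      for (j in (i + 1):nrow(pts)) {
        if (keep[j] && sqrt(sum((pts[i, ] - pts[j, ])^2)) < tol) {
          keep[j] <- FALSE
        }
      }
    }
  }
  pts[keep, , drop = FALSE]
}

#' Nullclines of a two-node rate system
#'
#' Zero-level sets of each component of the rate derivative, extracted as
#' ordered polylines from a regular grid (via contour tracing).
#'
#' @param system a two-node [rate_system()].
#' @param box `c(lo, hi)` bounds applied to both axes.
#' @param resolution grid points per axis.
#' @return list of two elements (`nc1`, `nc2`), each a list of data frames
#'   with columns `w1`, `w2` tracing the zero set of the corresponding
#'   component.
#' @export
nullclines <- function(system, box = c(0, 10), resolution = 201) {
  stopifnot(inherits(system, "rate_system"), system$n == 2)
  if (box[2] <= box[1]) stop("empty bounding box", call. = FALSE)
  ax <- seq(box[1], box[2], length.out = resolution)
  g <- expand.grid(w1 = ax, w2 = ax)
  d <- t(apply(g, 1, function(x) rate_rhs(as.numeric(x), system)))
  lines_of <- function(comp) {
    z <- matrix(d[, comp], resolution, resolution)  # z[i,j] = f(ax[i], ax[j])
    cl <- grDevices::contourLines(ax, ax, z, levels = 0)
    lapply(cl, function(l) data.frame(w1 = l$x, w2 = l$y))
  }
  list(nc1 = lines_of(1), nc2 = lines_of(2))
}

#' Polynomial least-squares fits to sampled nullclines
#'
#' Fits each sampled curve as a polynomial graph over its first coordinate
#' (the first nullcline as `w2 = P(w1)`, the second as `w1 = Q(w2)`),
#' restricted to the sampling window.  A fit is acceptable when the flow it
#' induces is qualitatively identical, which is checked by comparing the
#' number of nullcline intersections inside the window
#' ([count_intersections()]).
#'
#' @param curves output of [nullclines()].
#' @param degree polynomial degree.
#' @param window optional list with ranges `w1`, `w2`: only samples inside
#'   are fitted (the region of interest; rectified nullcline branches along
#'   the axes are poorly served by a single polynomial graph and are
#'   usually cropped away).
#' @return list with `p1`, `p2` (coefficient vectors, increasing powers)
#'   and `window` (the fit window).
#' @export
fit_polynomial_nullclines <- function(curves, degree = 5, window = NULL) {
  crop <- function(xy) {
    if (is.null(window)) return(xy)
    xy[xy$w1 >= window$w1[1] & xy$w1 <= window$w1[2] &
         xy$w2 >= window$w2[1] & xy$w2 <= window$w2[2], , drop = FALSE]
  }
  fit_one <- function(lines, swap = FALSE) {
    xy <- crop(do.call(rbind, lines))
    if (swap) xy <- xy[, 2:1]
    if (nrow(xy) < degree + 1) stop("not enough samples for degree ", degree,
                                    call. = FALSE)
    x <- xy[[1]]; y <- xy[[2]]
    co <- stats::coef(stats::lm(y ~ stats::poly(x, degree, raw = TRUE)))
    co[is.na(co)] <- 0
    unname(co)
  }
  xy_all <- crop(do.call(rbind, c(curves$nc1, curves$nc2)))
  list(p1 = fit_one(curves$nc1, swap = FALSE),
       p2 = fit_one(curves$nc2, swap = TRUE),
       window = if (is.null(window)) {
         list(w1 = range(xy_all$w1), w2 = range(xy_all$w2))
       } else window)
}

eval_poly <- function(coefs, x) {
  out <- 0
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}

#' Count nullcline intersections in a window
#'
#' For the source system the intersections are the fixed points inside the
#' window; for a polynomial fit (`fit`) the intersections of
#' `w2 = P(w1)` and `w1 = Q(w2)` are counted by sign changes of
#' `w1 - Q(P(w1))` on a dense grid.
#'
#' @param system a two-node [rate_system()] (used when `fit` is `NULL`).
#' @param fit result of [fit_polynomial_nullclines()].
#' @param window list with ranges `w1`, `w2` (defaults to the fit window).
#' @param grid_n evaluation grid size.
#' @return integer intersection count.
#' @export
count_intersections <- function(system = NULL, fit = NULL, window = NULL,
                                grid_n = 2000) {
  if (!is.null(fit)) {
    if (is.null(window)) window <- fit$window
    x <- seq(window$w1[1], window$w1[2], length.out = grid_n)
    y <- eval_poly(fit$p1, x)
    inside <- y >= window$w2[1] & y <= window$w2[2]
    res <- x - eval_poly(fit$p2, y)
    res[!inside] <- NA
    s <- sign(res)
    sum(diff(s[!is.na(s)]) != 0 & abs(diff(s[!is.na(s)])) == 2, na.rm = TRUE)
  } else {
    stopifnot(inherits(system, "rate_system"))
    if (is.null(window)) stop("need a window", call. = FALSE)
    fp <- find_fixed_points(system, box = range(unlist(window)), grid_n = 15)
    if (!nrow(fp)) return(0L)
    sum(fp$w1 >= window$w1[1] & fp$w1 <= window$w1[2] &
        fp$w2 >= window$w2[1] & fp$w2 <= window$w2[2])
  }
}

#' Error of the mean-rate approximation
#'
#' Log of the summed squared difference between two synaptic-drive
#' trajectories on a common time grid, e.g. the drive under the mean-rate
#' reduction versus the drive under an explicit spike-train surrogate.
#'
#' @param x,y numeric trajectories (same length).
#' @param floor value reported when the trajectories are identical
#'   (the log of zero error), default `-Inf` replaced by `-745`.
#' @return scalar `log(sum((x - y)^2))`.
#' @export
reduction_error <- function(x, y, floor = -745) {
  if (length(x) != length(y)) stop("trajectory grids do not match",
                                   call. = FALSE)
  sse <- sum((x - y)^2)
  if (sse == 0) floor else log(sse)
}

#' Synaptic-drive trajectory under a surrogate spike train
#'
#' Builds the drive variable omega(t) driven by a spike train that stands
#' in for a neuron firing at constant rate `rate`: either the deterministic
#' `"mean-rate"` flow (no spikes, continuous feed `k * rate`), an
#' `"equal-isi"` train, or a `"poisson"` train (seeded).
#'
#' @param rate firing rate (spikes/ms).
#' @param duration total time (ms).
#' @param dt sample step (ms).
#' @param k,tau_s drive parameters.
#' @param kind surrogate type.
#' @param seed RNG seed for the Poisson train.
#' @param omega0 initial drive value.
#' @return numeric trajectory sampled at `seq(0, duration, by = dt)`.
#' @export
surrogate_drive <- function(rate, duration, dt = 0.1, k = K_DEFAULT,
                            tau_s = 20,
                            kind = c("mean-rate", "equal-isi", "poisson"),
                            seed = 1L, omega0 = 0) {
  kind <- match.arg(kind)
  times <- seq(0, duration, by = dt)
  if (kind == "mean-rate") {
    # omega' = -omega/tau + k r  ->  exact exponential relaxation
    target <- k * rate * tau_s
    return(target + (omega0 - target) * exp(-times / tau_s))
  }
  spikes <- if (kind == "equal-isi") {
    if (rate <= 0) numeric(0) else seq(1 / rate, duration, by = 1 / rate)
  } else {
    with_seed(seed, {
      n_exp <- stats::rpois(1, rate * duration * 1.5) + 20
      s <- cumsum(stats::rexp(n_exp, rate))
      s[s <= duration]
    })
  }
  omega <- numeric(length(times))
  omega[1] <- omega0
  cur <- omega0
  t_prev <- 0
  si <- 1
  for (i in seq_along(times)[-1]) {
    t_next <- times[i]
    while (si <= length(spikes) && spikes[si] <= t_next) {
      cur <- cur * exp(-(spikes[si] - t_prev) / tau_s) + k
      t_prev <- spikes[si]
      si <- si + 1
    }
    cur <- cur * exp(-(t_next - t_prev) / tau_s)
    t_prev <- t_next
    omega[i] <- cur
  }
  omega
}
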