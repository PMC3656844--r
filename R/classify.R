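# Attractor classification of low-dimensional flows.
#
# The protocol: locate fixed points by multi-start root finding, assess
# their linear stability, simulate to detect sustained oscillation, and
# probe a single stable fixed point with small and large kicks to separate
# plain fixed-point relaxation from monostable (excitable) dynamics, where
# a suprathreshold perturbation rides a large transient before returning.

FLOW_LABELS <- c("FIXED_POINT", "LIMIT_CYCLE", "BISTABLE", "MONOSTABLE",
                 "MULTISTABLE", "UNCLASSIFIED")

#' Classify the attractor structure of a flow
#'
#' @param x a [rate_system()], or a plain vector field `function(state)`.
#' @param ... passed to the workhorse [classify_field()].
#' @return a `flow_report`: list with `classification`, `fixed_points`
#'   (data frame from [find_fixed_points()]), `oscillatory`, and the
#'   perturbation-protocol log.
#' @export
classify_flow <- function(x, ...) UseMethod("classify_flow")

#' @rdname classify_flow
#' @export
classify_flow.rate_system <- function(x, box = NULL, ...) {
  if (is.null(box)) {
    # generous default: drive-free relaxation keeps omega below the
    # uncoupled high-rate scale
    scale <- if (x$simplified) max(1, max(abs(x$input))) * 4
             else (x$k * x$tau_s / pi)^2 * 2 + max(abs(x$input)) * 2
    box <- c(0, max(2, scale))
  }
  classify_field(function(w) rate_rhs(w, x), n = x$n, box = box,
                 tau = x$tau_s, system = x, ...)
}

#' @rdname classify_flow
#' @export
classify_flow.function <- function(x, n = 2, box = c(-3, 3), tau = 1, ...) {
  classify_field(x, n = n, box = box, tau = tau, ...)
}

#' Workhorse classifier for a generic vector field
#'
#' @param f vector field `function(state) -> derivative`.
#' @param n state dimension.
#' @param box `c(lo, hi)` search/simulation box per coordinate.
#' @param tau characteristic timescale; transients of `10 * tau` are
#'   discarded before oscillation detection.
#' @param grid_n root-search grid points per axis.
#' @param seed seed for the randomised probe directions.
#' @param small_kick,large_kick perturbation amplitudes as fractions of the
#'   attractor scale.
#' @param excursion_factor a large kick whose maximal excursion exceeds
#'   this multiple of the kick size flags monostable (excitable) dynamics.
#' @param min_amp minimal peak-to-peak amplitude for oscillation.
#' @param dt integration step for the probes.
#' @return a `flow_report`.
#' @export
classify_field <- function(f, n, box, tau = 1, grid_n = NULL, seed = 1L,
                           small_kick = 0.01, large_kick = 0.5,
                           excursion_factor = 1.8, min_amp = 1e-3,
                           dt = tau / 40, system = NULL) {
  fps <- if (is.null(system)) {
    find_fixed_points(f = f, box = box, grid_n = grid_n, n = n)
  } else {
    find_fixed_points(system = system, box = box, grid_n = grid_n)
  }
  stable <- fps[fps$stable, , drop = FALSE]
  span <- box[2] - box[1]
  horizon <- 50 * tau
  transient_t <- 10 * tau

  # oscillation probes from dispersed initial conditions
  inits <- probe_inits(n, box, seed)
  osc <- FALSE; osc_traj <- NULL
  for (i in seq_len(nrow(inits))) {
    tr <- rk4_field(f, inits[i, ], horizon, dt)
    tail_tr <- tr[tr[, 1] >= transient_t, -1, drop = FALSE]
    if (is_oscillatory(tail_tr, min_amp * span)) {
      osc <- TRUE; osc_traj <- tr; break
    }
  }

  protocol <- list()
  label <- if (nrow(stable) >= 3) "MULTISTABLE"
    else if (nrow(stable) == 2) "BISTABLE"
    else if (nrow(stable) == 0 && osc) "LIMIT_CYCLE"
    else if (nrow(stable) == 1 && osc) "LIMIT_CYCLE"
    else if (nrow(stable) == 1) {
      fp <- as.numeric(stable[1, seq_len(n)])
      scale <- max(sqrt(sum(fp^2)), 0.1 * span)
      amp <- kick_amplification(f, fp, scale * large_kick, horizon, dt, seed)
      amp_small <- kick_amplification(f, fp, scale * small_kick, horizon, dt,
                                      seed)
      protocol <- list(large = amp, small = amp_small)
      if (amp$returned && amp$amplification > excursion_factor &&
          amp_small$amplification <= excursion_factor) "MONOSTABLE"
      else "FIXED_POINT"
    } else "UNCLASSIFIED"

  structure(list(classification = label, fixed_points = fps,
                 oscillatory = osc, protocol = protocol,
                 evidence = osc_traj),
            class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat("<flow_report>", x$classification, "|",
      sum(x$fixed_points$stable), "stable /", nrow(x$fixed_points),
      "fixed points | oscillatory:", x$oscillatory, "\n")
  invisible(x)
}

probe_inits <- function(n, box, seed) {
  span <- box[2] - box[1]
  base <- rbind(rep(mean(box), n),
                rep(box[1] + 0.9 * span, n),
                rep(box[1] + 0.1 * span, n))
  extra <- with_seed(seed, matrix(stats::runif(3 * n, box[1] + 0.05 * span,
                                               box[2] - 0.05 * span),
                                  ncol = n))
  rbind(base, extra, diag(0.8 * span, n) + box[1] + 0.05 * span)
}

# Probe a stable fixed point with kicks in +/- coordinate directions and
# diagonals; report the worst-case excursion relative to the kick size and
# whether the state returned to the fixed point.
kick_amplification <- function(f, fp, kick, horizon, dt, seed) {
  n <- length(fp)
  dirs <- rbind(diag(n), -diag(n))
  if (n >= 2) {
    # all +/-1 sign combinations (diagonal compass directions)
    combs <- as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
    dirs <- rbind(dirs, combs / sqrt(n))
    dirs <- rbind(dirs, with_seed(seed + 1, {
      d <- matrix(stats::rnorm(4 * n), ncol = n)
      d / sqrt(rowSums(d^2))
    }))
  }
  best <- 0; returned <- TRUE
  for (i in seq_len(nrow(dirs))) {
    x0 <- fp + kick * dirs[i, ]
    tr <- rk4_field(f, x0, horizon, dt)
    d <- sqrt(rowSums((tr[, -1, drop = FALSE] -
                         matrix(fp, nrow(tr), n, byrow = TRUE))^2))
    best <- max(best, max(d) / kick)
    if (d[length(d)] > max(kick, 0.05 * max(d))) returned <- FALSE
  }
  list(amplification = best, returned = returned, kick = kick)
}

#' Fixed-step integration of a plain vector field
#'
#' @param f vector field.
#' @param x0 initial state.
#' @param duration,dt time span and step.
#' @return matrix: time column followed by state columns.
#' @export
rk4_field <- function(f, x0, duration, dt) {
  nstep <- max(1L, floor(duration / dt))
  out <- matrix(NA_real_, nstep + 1, length(x0) + 1)
  out[1, ] <- c(0, x0)
  x <- x0
  for (s in seq_len(nstep)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1, ] <- c(s * dt, x)
  }
  out
}

# Sustained oscillation: peak-to-peak amplitude above `min_amp` in the
# post-transient window and an autocorrelation that recovers above 0.5 at a
# nonzero lag (a repeating period).
is_oscillatory <- function(traj, min_amp) {
  if (is.null(dim(traj))) traj <- matrix(traj, ncol = 1)
  if (nrow(traj) < 16) return(FALSE)
  amps <- apply(traj, 2, function(z) diff(range(z)))
  if (max(amps) < min_amp) return(FALSE)
  z <- traj[, which.max(amps)]
  z <- z - mean(z)
  if (stats::sd(z) == 0) return(FALSE)
  a <- stats::acf(z, lag.max = floor(length(z) / 2), plot = FALSE)$acf[, 1, 1]
  # first local minimum, then require recovery above 0.5 afterwards
  dmin <- which(diff(a) > 0)[1]
  if (is.na(dmin)) return(FALSE)
  any(a[(dmin + 1):length(a)] > 0.5)
}

#' Classify a flow from simulated trajectories
#'
#' Trajectory-level counterpart of [classify_field()] used for the spiking
#' network, whose drive variables are only observable through (jagged)
#' simulation output.  `runs` are tail-aligned trajectories started from
#' dispersed initial conditions; `kicked` (optional) are runs restarted
#' from a settled state with a large perturbation.
#'
#' @param runs list of matrices (time column + state columns), already
#'   smoothed if they come from spike-driven simulation.
#' @param transient_t time to discard.
#' @param settle_tol distinct settled states further apart than this are
#'   separate attractors.
#' @param min_amp oscillation amplitude threshold.
#' @param kicked optional list of perturbed runs (each a list with `traj`,
#'   `fp`, `kick`).
#' @param excursion_factor as in [classify_field()].
#' @return a `flow_report` (without root-finding evidence).
#' @export
classify_trajectories <- function(runs, transient_t, settle_tol, min_amp,
                                  kicked = NULL, excursion_factor = 1.8) {
  tails <- lapply(runs, function(tr) tr[tr[, 1] >= transient_t, -1,
                                        drop = FALSE])
  osc <- any(vapply(tails, is_oscillatory, logical(1), min_amp = min_amp))
  settles <- do.call(rbind, lapply(tails, function(z) {
    colMeans(z[max(1, nrow(z) - 50):nrow(z), , drop = FALSE])
  }))
  # cluster settled states
  if (!osc) {
    reps <- settles[1, , drop = FALSE]
    for (i in seq_len(nrow(settles))[-1]) {
      d <- apply(reps, 1, function(r) sqrt(sum((r - settles[i, ])^2)))
      if (min(d) > settle_tol) reps <- rbind(reps, settles[i, ])
    }
    n_att <- nrow(reps)
  } else n_att <- 0L

  label <- if (osc) "LIMIT_CYCLE"
    else if (n_att >= 3) "MULTISTABLE"
    else if (n_att == 2) "BISTABLE"
    else if (n_att == 1) {
      mono <- FALSE
      if (!is.null(kicked)) {
        for (kr in kicked) {
          d <- sqrt(rowSums((kr$traj[, -1, drop = FALSE] -
                               matrix(kr$fp, nrow(kr$traj), length(kr$fp),
                                      byrow = TRUE))^2))
          ret <- d[length(d)] < max(2 * settle_tol, kr$kick)
          if (ret && max(d) / kr$kick > excursion_factor) mono <- TRUE
        }
      }
      if (mono) "MONOSTABLE" else "FIXED_POINT"
    } else "UNCLASSIFIED"

  structure(list(classification = label, oscillatory = osc,
                 settled = if (!osc) reps else NULL,
                 fixed_points = data.frame(stable = logical(0)),
                 protocol = list()),
            class = "flow_report")
}

#' Classify the flow realised by the spiking network
#'
#' Runs the full spiking model from dispersed drive-variable initial
#' conditions (random seeded phases), smooths the jagged drive trajectories,
#' and applies [classify_trajectories()]; a single settled state is probed
#' with large kicks to separate plain relaxation from monostable
#' (excitable) dynamics.  This is the trajectory-level counterpart of
#' [classify_flow()] used to check that the spiking network realises the
#' same flow as its rate reduction.
#'
#' @param params a [network_params()].
#' @param input constant per-neuron drive.
#' @param box `c(lo, hi)` range of the drive-variable initial conditions.
#' @param seed RNG seed (phases).
#' @param duration run length per probe (ms).
#' @param dt integration step (ms).
#' @param smooth_ms moving-average window applied to the drive traces (ms).
#' @param settle_frac settled states closer than this fraction of the box
#'   span are considered the same attractor.
#' @param min_amp_frac oscillation threshold as a fraction of the span.
#' @return a `flow_report`.
#' @export
classify_flow_spiking <- function(params, input, box = c(0, 10), seed = 1L,
                                  duration = 60 * params$tau_s, dt = 0.05,
                                  smooth_ms = 41, settle_frac = 0.12,
                                  min_amp_frac = 0.1) {
  n <- params$n
  span <- box[2] - box[1]
  tau <- params$tau_s
  run <- function(w0, sd_off = 0L) {
    sim <- simulate_network(params, input,
                            init = list(theta = with_seed(seed + sd_off,
                              stats::runif(n, 0, 2 * pi)), omega = w0),
                            duration = duration, dt = dt, record_every = 1)
    sm <- smooth_traces(sim$omega, smooth_ms)
    cbind(sim$time, t(sm))
  }
  # probes are deliberately asymmetric: exactly symmetric states can sit on
  # rate-unstable but spiking-stabilised configurations
  ramp <- 1 + 0.3 * (seq_len(n) - (n + 1) / 2) / max(n - 1, 1)
  inits <- list(mean(box) * ramp,
                (box[1] + 0.8 * span) * rev(ramp),
                box[1] + 0.85 * span * (seq_len(n) == 1),
                box[1] + 0.85 * span * (seq_len(n) == n))
  runs <- lapply(seq_along(inits), function(i) run(inits[[i]], i))
  settle_tol <- settle_frac * span
  min_amp <- min_amp_frac * span
  rep0 <- classify_trajectories(runs, transient_t = 15 * tau,
                                settle_tol = settle_tol, min_amp = min_amp)
  if (rep0$classification != "FIXED_POINT") return(rep0)
  # probe the single settled state with large kicks
  fp <- as.numeric(rep0$settled[1, ])
  kick <- 0.5 * max(sqrt(sum(fp^2)), 0.1 * span)
  dirs <- as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n))) / sqrt(n)
  dirs <- rbind(dirs, diag(n), -diag(n))
  kicked <- lapply(seq_len(nrow(dirs)), function(i) {
    w0 <- pmax(fp + kick * dirs[i, ], 0)
    list(traj = run(w0, 100L + i), fp = fp, kick = kick)
  })
  classify_trajectories(runs, transient_t = 15 * tau,
                        settle_tol = settle_tol, min_amp = min_amp,
                        kicked = kicked)
}

#' Moving-average smoothing of a trajectory matrix
#'
#' @param x matrix with one row per neuron (as in `sim_result$omega`).
#' @param width window width in samples.
#' @return smoothed matrix of the same shape.
#' @export
smooth_traces <- function(x, width) {
  if (width <= 1) return(x)
  kern <- rep(1 / width, width)
  t(apply(x, 1, function(z) {
    as.numeric(stats::filter(z, kern, sides = 2)) -> s
    # fill the ends with the nearest valid value
    idx <- which(!is.na(s))
    s[seq_len(idx[1] - 1)] <- s[idx[1]]
    s[seq((idx[length(idx)] + 1), length.out = length(s) - idx[length(idx)])] <-
      s[idx[length(idx)]]
    s
  }))
}
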