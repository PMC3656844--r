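#' Network parameters for the spiking model
#'
#' Bundles the neuron count, coupling matrix and timescale constants of the
#' spiking network.  `coupling[i, j]` is the weight from presynaptic neuron
#' `j` to postsynaptic neuron `i`.
#'
#' @param coupling square numeric matrix of coupling weights (row =
#'   postsynaptic).
#' @param tau_s synaptic timescale in ms (default 20).
#' @param k spike-effect strength: instantaneous increment applied to a
#'   neuron's drive variable at each of its own spikes (scalar, or one
#'   value per neuron).
#' @param theta_timescale fast-timescale constant of the phase equation
#'   (default 1).
#' @return object of class `network_params`.
#' @export
network_params <- function(coupling, tau_s = 20, k = K_DEFAULT,
                           theta_timescale = 1) {
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != ncol(coupling)) {
    stop("coupling must be square", call. = FALSE)
  }
  if (!all(is.finite(coupling))) stop("coupling must be finite", call. = FALSE)
  if (!is.numeric(tau_s) || length(tau_s) != 1 || tau_s <= 0) {
    stop("tau_s must be a positive scalar", call. = FALSE)
  }
  if (nrow(coupling) < 1) stop("need at least one neuron", call. = FALSE)
  k <- rep_len(k, nrow(coupling))
  structure(
    list(n = nrow(coupling), coupling = coupling, tau_s = tau_s, k = k,
         theta_timescale = theta_timescale),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> n =", x$n,
      "| tau_s =", x$tau_s, "ms | k =", signif(mean(x$k), 3), "\n")
  invisible(x)
}

#' Piecewise-constant per-neuron input schedule
#'
#' @param breaks strictly increasing vector of segment start times (ms);
#'   the first entry is the start of the covered interval.
#' @param values numeric matrix with one row per segment and one column per
#'   neuron (a vector is treated as a single segment, or a single neuron
#'   column if `n` says so).
#' @param n neuron count (used to validate/recycle `values`).
#' @return object of class `input_schedule`: a function of time returning
#'   the per-neuron drive, with the breakpoint data attached.
#' @export
input_schedule <- function(breaks, values, n = NULL) {
  breaks <- as.numeric(breaks)
  if (any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  if (is.null(dim(values))) {
    values <- if (length(breaks) == 1) matrix(values, nrow = 1)
              else matrix(values, nrow = length(breaks))
  }
  values <- as.matrix(values)
  if (!is.null(n) && ncol(values) == 1 && n > 1) {
    values <- values[, rep(1, n), drop = FALSE]
  }
  if (nrow(values) != length(breaks)) {
    stop("values must have one row per break", call. = FALSE)
  }
  f <- function(t) {
    i <- findInterval(t, breaks)
    if (i < 1) i <- 1
    values[i, ]
  }
  structure(f, breaks = breaks, values = values, class = "input_schedule")
}

#' Constant input schedule helper
#' @param value per-neuron drive (scalar or vector).
#' @param n neuron count.
#' @export
constant_input <- function(value, n) {
  input_schedule(0, matrix(rep_len(value, n), nrow = 1), n = n)
}

#' Simulate the spiking network
#'
#' Fixed-step integration (classical Runge-Kutta on the smooth part) of the
#' coupled phase/synaptic-drive system.  A spike is an upward crossing of
#' the phase threshold; the crossing time is located by linear
#' interpolation within the step and the spiking neuron's drive variable
#' receives an instantaneous increment `k`.  The phase variable itself is
#' continuous through the spike and is kept wrapped in `[0, 2*pi)`.
#'
#' @param params a [network_params()] object.
#' @param input an [input_schedule()], or a numeric vector/scalar treated
#'   as constant drive.
#' @param init list with numeric vectors `theta` and `omega`, or `NULL` to
#'   draw uniform random phases (seeded) with zero initial drive.
#' @param duration total simulated time (ms).
#' @param dt integration step (ms, default 0.05).
#' @param seed integer seed controlling the random initial condition; the
#'   integration itself is deterministic.
#' @param record_every store the state every this many ms (default `dt`).
#' @return object of class `sim_result` with fields `time`, `theta` and
#'   `omega` (matrices, one row per neuron), `spikes` (data frame `t`,
#'   `neuron`, sorted by time), `dt`, `seed`.
#' @export
simulate_network <- function(params, input, init = NULL, duration,
                             dt = 0.05, seed = 1L, record_every = dt) {
  stopifnot(inherits(params, "network_params"))
  if (!(is.numeric(dt) && dt > 0)) stop("dt must be > 0", call. = FALSE)
  if (duration < 0) stop("duration must be nonnegative", call. = FALSE)
  n <- params$n
  if (is.numeric(input)) input <- constant_input(input, n)
  stopifnot(inherits(input, "input_schedule"))

  if (is.null(init)) {
    init <- with_seed(seed, list(theta = stats::runif(n, 0, 2 * pi),
                                 omega = numeric(n)))
  }
  theta <- wrap_phase(as.numeric(init$theta))
  omega <- as.numeric(init$omega)
  if (length(theta) != n || length(omega) != n) {
    stop("init dimensions do not match params$n", call. = FALSE)
  }

  nstep <- floor(duration / dt + 1e-9)
  rec_stride <- max(1L, round(record_every / dt))
  nrec <- floor(nstep / rec_stride) + 1L
  theta_tr <- matrix(NA_real_, n, nrec)
  omega_tr <- matrix(NA_real_, n, nrec)
  times <- numeric(nrec)
  theta_tr[, 1] <- theta; omega_tr[, 1] <- omega
  spk_t <- numeric(0); spk_i <- integer(0)

  C <- params$coupling
  tau <- params$tau_s
  tth <- params$theta_timescale
  rhs <- function(theta, omega, inp) {
    drive <- inp + as.vector(C %*% omega)
    list(dth = ((1 - cos(theta)) + (1 + cos(theta)) * drive) / tth,
         dom = -omega / tau)
  }

  irec <- 1L
  for (s in seq_len(nstep)) {
    t0 <- (s - 1) * dt
    inp <- input(t0)
    k1 <- rhs(theta, omega, inp)
    inp_h <- input(t0 + dt / 2)
    k2 <- rhs(theta + dt / 2 * k1$dth, omega + dt / 2 * k1$dom, inp_h)
    k3 <- rhs(theta + dt / 2 * k2$dth, omega + dt / 2 * k2$dom, inp_h)
    inp_1 <- input(t0 + dt)
    k4 <- rhs(theta + dt * k3$dth, omega + dt * k3$dom, inp_1)
    th_new <- theta + dt / 6 * (k1$dth + 2 * k2$dth + 2 * k3$dth + k4$dth)
    om_new <- omega + dt / 6 * (k1$dom + 2 * k2$dom + 2 * k3$dom + k4$dom)

    if (!all(is.finite(th_new)) || !all(is.finite(om_new))) {
      stop("non-finite state at t = ", t0 + dt,
           " ms; reduce dt or check parameters", call. = FALSE)
    }

    # spike = upward crossing of THETA_SPIKE within the step (the phase
    # velocity at the threshold is 2/tau_theta > 0, so crossings are
    # always upward)
    crossed <- theta < THETA_SPIKE & th_new >= THETA_SPIKE
    if (any(crossed)) {
      idx <- which(crossed)
      frac <- (THETA_SPIKE - theta[idx]) / (th_new[idx] - theta[idx])
      t_star <- t0 + frac * dt
      om_new[idx] <- om_new[idx] + params$k[idx]
      spk_t <- c(spk_t, t_star)
      spk_i <- c(spk_i, idx)
    }

    theta <- wrap_phase(th_new)
    omega <- om_new
    if (s %% rec_stride == 0L) {
      irec <- irec + 1L
      theta_tr[, irec] <- theta
      omega_tr[, irec] <- omega
      times[irec] <- s * dt
    }
  }

  ord <- order(spk_t)
  spikes <- data.frame(t = spk_t[ord], neuron = spk_i[ord])
  structure(
    list(time = times[seq_len(irec)],
         theta = theta_tr[, seq_len(irec), drop = FALSE],
         omega = omega_tr[, seq_len(irec), drop = FALSE],
         spikes = spikes, dt = dt, seed = seed, params = params),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", nrow(x$theta), "neurons,",
      length(x$time), "samples,", nrow(x$spikes), "spikes, dt =", x$dt, "ms\n")
  invisible(x)
}

#' Interspike intervals of one neuron
#' @param sim a `sim_result`.
#' @param neuron neuron index.
#' @return numeric vector of ISIs (ms).
#' @export
interspike_intervals <- function(sim, neuron = 1) {
  t <- sim$spikes$t[sim$spikes$neuron == neuron]
  diff(t)
}

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the generator seeded by `seed` and restores the
#' caller's RNG state afterwards, so seeded draws never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
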