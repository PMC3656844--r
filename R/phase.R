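# Spike-timing (phase) reduction.
#
# On short timescales the drive variables are frozen: each neuron is a
# bare oscillator with constant effective drive eta_i > 0 (period
# T = pi/sqrt(eta)), and presynaptic spikes act as delta perturbations of
# the phase equation.  The pulse convention: a spike of weight kappa
# multiplies the rate-of-rise term, dtheta/dt = (1 - cos theta)(1 +
# kappa delta(t)) + (1 + cos theta) eta.  In the half-angle chart
# u = tan(theta/2) the free flow is the Riccati equation du/dt = u^2 + eta
# and the pulse is the exact Mobius step u -> u/(1 - kappa u), so the
# network can be simulated event-by-event with no integration error.  A
# strong enough excitatory pulse carries a late-phase receiver across
# threshold (absorption), which is what lets positive coupling synchronise
# the network; modulating the input term (1 + cos theta) instead yields a
# unimodal response that never synchronises excitatorily.  Internally each
# oscillator is stored as the linear phase psi = atan(u/sqrt(eta)) in
# (-pi/2, pi/2], which advances at the constant rate sqrt(eta); the
# conventional phase is phi = 2 psi + pi in [0, 2 pi), with the spike at
# phi = 2 pi == 0.

# Apply a pulse of weight kappa to oscillators at linear phase psi with
# sqrt-drive sqeta.  Returns the new psi and whether the pulse carried the
# oscillator across threshold (it should be treated as spiking now).
pulse_map <- function(psi, kappa, sqeta) {
  u <- sqeta * tan(psi)
  den <- 1 - kappa * u
  u_new <- u / den
  fired <- (kappa > 0 & den < 0)
  # inhibitory wrap backward across the reset point: clamp to just-reset
  # rather than un-spiking the neuron
  unspiked <- (kappa < 0 & den < 0)
  psi_new <- atan(u_new / sqeta)
  psi_new[unspiked] <- -pi / 2
  list(psi = psi_new, fired = fired)
}

#' Pulse-coupled phase network
#'
#' @param Omega per-neuron angular frequencies (rad/ms); the averaged
#'   firing of the full model is absorbed here (`Omega = 2 * sqrt(eta)`
#'   for effective drive `eta`).
#' @param coupling matrix of pulse weights: `coupling[i, j]` is the pulse
#'   weight from `j` to `i` (the area of the relative modulation of the
#'   receiver's rate-of-rise term).
#' @param tau_c synaptic kernel timescale (ms) used by the averaged
#'   interaction ([filtered_prc()], [simulate_phase_coupled()]); the
#'   event-driven simulator treats pulses as instantaneous (`tau_c` is the
#'   short synaptic filter whose skew gives locked states their linear
#'   stability; the delta limit is neutrally stable).
#' @return object of class `phase_network`.
#' @export
phase_network <- function(Omega, coupling, tau_c = 2) {
  coupling <- as.matrix(coupling)
  n <- nrow(coupling)
  Omega <- rep_len(Omega, n)
  if (any(Omega <= 0)) stop("oscillating units need Omega > 0", call. = FALSE)
  if (ncol(coupling) != n) stop("coupling must be square", call. = FALSE)
  structure(list(n = n, Omega = Omega, coupling = coupling,
                 sqeta = Omega / 2, tau_c = tau_c),
            class = "phase_network")
}

#' Synaptically filtered phase response (linear response)
#'
#' Phase shift, per unit pulse, when the pulse is smeared by an exponential
#' synaptic kernel of timescale `tau_c` instead of arriving as a delta.
#' To linear order in the coupling the shift is the kernel-weighted average
#' of the oscillator's sensitivity \eqn{(1+\cos\varphi)/\sqrt\eta}:
#' \deqn{g_f(\varphi) = \frac{\kappa}{\sqrt\eta}\left[1 +
#'   \frac{\cos\varphi - \Omega\tau_c \sin\varphi}{1 + \Omega^2\tau_c^2}
#'   \right].}
#' The \eqn{-\Omega\tau_c\sin\varphi} skew (the lag of the synaptic kernel)
#' is what makes the synchronous state linearly stable for positive
#' coupling; in the delta limit `tau_c -> 0` the curve is symmetric and
#' locking is only neutrally stable.
#'
#' @inheritParams analytic_prc
#' @param tau_c synaptic kernel timescale (ms).
#' @return phase shift(s), radians.
#' @export
filtered_prc <- function(phi, coupling, Omega = 2 * pi / 20, tau_c = 2) {
  sqeta <- Omega / 2
  (coupling / sqeta) *
    (1 + (cos(phi) - Omega * tau_c * sin(phi)) / (1 + (Omega * tau_c)^2))
}

#' @rdname filtered_prc
#' @export
filtered_prc_slope <- function(phi, coupling, Omega = 2 * pi / 20,
                               tau_c = 2) {
  sqeta <- Omega / 2
  (coupling / sqeta) *
    (-sin(phi) - Omega * tau_c * cos(phi)) / (1 + (Omega * tau_c)^2)
}

#' @export
print.phase_network <- function(x, ...) {
  cat("<phase_network> n =", x$n, "| mean period =",
      signif(mean(2 * pi / x$Omega), 4), "ms\n")
  invisible(x)
}

#' Closed-form phase response curve of the theta-style oscillator
#'
#' Exact phase shift caused by a delta pulse of weight `coupling` arriving
#' when the oscillator is at linear phase `phi` (radians since its last
#' spike, `[0, 2*pi)`).  With the pulse acting multiplicatively on the
#' rate-of-rise term, the half-angle coordinate \eqn{u = \tan(\theta/2)}
#' jumps to \eqn{u/(1-\kappa u)} and the shift is
#' \deqn{g(\varphi) = 2[\arctan(u'/\sqrt\eta) - \arctan(u/\sqrt\eta)]}
#' (plus \eqn{\pi} when an excitatory pulse carries the oscillator across
#' threshold), with \eqn{u = \sqrt\eta \tan((\varphi-\pi)/2)} and
#' \eqn{\eta = (\Omega/2)^2}.  The curve is identically zero at zero
#' coupling, 2*pi-periodic, vanishes at mid-cycle, and is bimodal with the
#' stronger lobe on the late-phase side for excitatory coupling (early side
#' for inhibitory).  Positive values are phase advances.
#'
#' @param phi phase(s) at pulse arrival, radians.
#' @param coupling pulse weight `kappa` (delta area of the relative
#'   modulation of the rate-of-rise term).
#' @param Omega angular frequency of the unperturbed oscillator (rad/ms).
#' @return phase shift(s), radians.
#' @export
analytic_prc <- function(phi, coupling, Omega = 2 * pi / 20) {
  n_out <- max(length(phi), length(coupling), length(Omega))
  phi <- rep_len(phi, n_out)
  coupling <- rep_len(as.vector(coupling), n_out)
  Omega <- rep_len(as.vector(Omega), n_out)
  sqeta <- Omega / 2
  psi <- (phi %% (2 * pi) - pi) / 2
  u <- sqeta * tan(psi)
  den <- 1 - coupling * u
  u_new <- u / den
  psi_new <- atan(u_new / sqeta)
  crossed <- coupling > 0 & den < 0
  psi_new[crossed] <- psi_new[crossed] + pi
  unspiked <- coupling < 0 & den < 0
  psi_new[unspiked] <- -pi / 2
  out <- 2 * (psi_new - psi)
  out[coupling == 0] <- 0
  out[!is.finite(u)] <- 0     # exactly at the spike point
  out
}

#' Slope of the analytic phase response curve
#' @inheritParams analytic_prc
#' @param h central-difference step.
#' @export
prc_slope <- function(phi, coupling, Omega = 2 * pi / 20, h = 1e-6) {
  (analytic_prc(phi + h, coupling, Omega) -
     analytic_prc(phi - h, coupling, Omega)) / (2 * h)
}

#' Simulated phase response curve
#'
#' Independent measurement of the PRC: the full phase equation is
#' integrated (classical Runge-Kutta) with the presynaptic spike realised
#' as a narrow rectangular modulation of the rate-of-rise term with the
#' same area, and the shift is read from the asymptotic displacement of the
#' spike times (by default 10 cycles after the perturbation), converted to
#' phase.
#'
#' @param eta effective drive of the postsynaptic oscillator (> 0).
#' @param coupling pulse area.
#' @param phi phases at which to probe (vector); the default is a 64-point
#'   grid over the open cycle (the exact spike instant is excluded: a pulse
#'   arriving simultaneously with the spike is an ordering convention, not
#'   a response measurement).
#' @param n_cycles cycles to wait before reading the shift.
#' @param dt integration step (ms).
#' @param width pulse width (ms; snapped to a multiple of `dt`).
#' @return data frame with `phi` and `shift` (radians).
#' @export
numerical_prc <- function(eta, coupling,
                          phi = seq_len(64) / 65 * 2 * pi,
                          n_cycles = 10, dt = 0.005, width = 0.05) {
  if (eta <= 0) stop("postsynaptic neuron must be oscillating (eta > 0)",
                     call. = FALSE)
  T0 <- closed_form_period(eta)
  # an inhibitory modulation must keep the rate-of-rise factor nonnegative,
  # so the pulse cannot be narrower than its own magnitude
  if (coupling < 0) width <- max(width, 1.25 * abs(coupling))
  width <- max(dt, round(width / dt) * dt)
  m <- length(phi)
  # copy 0 is the unperturbed reference
  t_pulse <- c(Inf, round((2 * T0 + phi / (2 * pi) * T0) / dt) * dt)
  amp <- coupling / width
  theta <- rep(THETA_SPIKE, m + 1)
  horizon <- (n_cycles + 4) * T0
  nstep <- ceiling(horizon / dt)
  n_spk <- integer(m + 1)
  t_spk <- matrix(NA_real_, m + 1, n_cycles + 4)
  for (s in seq_len(nstep)) {
    t0 <- (s - 1) * dt
    mod <- function(tt) 1 + amp * (tt >= t_pulse & tt < t_pulse + width)
    f <- function(th, tt) (1 - cos(th)) * mod(tt) + (1 + cos(th)) * eta
    k1 <- f(theta, t0)
    k2 <- f(theta + dt / 2 * k1, t0 + dt / 2)
    k3 <- f(theta + dt / 2 * k2, t0 + dt / 2)
    k4 <- f(theta + dt * k3, t0 + dt)
    th_new <- theta + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    crossed <- which(theta < THETA_SPIKE & th_new >= THETA_SPIKE)
    for (i in crossed) {
      n_spk[i] <- n_spk[i] + 1L
      if (n_spk[i] <= ncol(t_spk)) {
        t_spk[i, n_spk[i]] <- t0 + dt *
          (THETA_SPIKE - theta[i]) / (th_new[i] - theta[i])
      }
    }
    theta <- wrap_phase(th_new)
  }
  k_read <- min(n_spk) # common spike index, after the perturbed cycles
  shift <- 2 * pi * (t_spk[1, k_read] - t_spk[-1, k_read]) / T0
  data.frame(phi = phi, shift = shift)
}

#' Phase derivatives with pulse increments
#'
#' The drift part is the constant rotation `Omega`; spikes of the listed
#' presynaptic neurons contribute instantaneous phase jumps given by the
#' analytic PRC at each receiver's current phase.
#'
#' @param phases current phases (radians, `[0, 2*pi)`).
#' @param network a [phase_network()].
#' @param spiking integer indices of neurons emitting a spike now.
#' @return list with `drift` (rad/ms) and `jump` (radians).
#' @export
phase_rhs <- function(phases, network, spiking = integer(0)) {
  stopifnot(inherits(network, "phase_network"))
  if (length(phases) != network$n) stop("dimension mismatch", call. = FALSE)
  jump <- numeric(network$n)
  for (j in spiking) {
    kij <- network$coupling[, j]
    idx <- which(kij != 0 & seq_len(network$n) != j)
    if (length(idx)) {
      jump[idx] <- jump[idx] +
        analytic_prc(phases[idx], kij[idx], network$Omega[idx])
    }
  }
  list(drift = network$Omega, jump = jump)
}

#' Event-driven simulation of the pulse-coupled phase network
#'
#' Exact between events; pulses are applied in the half-angle chart.
#' Simultaneous spikes are processed in neuron-index order (a convention;
#' its effect vanishes with event density).
#'
#' @param network a [phase_network()].
#' @param duration total time (ms).
#' @param init initial phases (radians), or `NULL` for seeded uniform
#'   random phases.
#' @param seed RNG seed for the initial condition.
#' @param record_dt sampling interval of the phase snapshots (ms).
#' @return list with `time`, `phases` (n x samples matrix, radians),
#'   `spikes` (data frame `t`, `neuron`).
#' @export
simulate_phase_network <- function(network, duration, init = NULL,
                                   seed = 1L, record_dt = 1) {
  stopifnot(inherits(network, "phase_network"))
  n <- network$n
  if (is.null(init)) {
    init <- with_seed(seed, stats::runif(n, 0, 2 * pi))
  }
  psi <- (wrap_phase(init) - pi) / 2
  sqeta <- network$sqeta
  K <- network$coupling
  rec_t <- seq(0, duration, by = record_dt)
  phases <- matrix(NA_real_, n, length(rec_t))
  irec <- 1L
  t <- 0
  spk_t <- numeric(0); spk_i <- integer(0)
  guard <- 0L
  max_events <- 1e7
  while (t < duration && guard < max_events) {
    guard <- guard + 1L
    rem <- (pi / 2 - psi) / sqeta
    j <- which.min(rem)
    dt_ev <- max(rem[j], 0)
    t_next <- t + dt_ev
    # record snapshots crossed by this free-flight segment
    while (irec <= length(rec_t) && rec_t[irec] <= min(t_next, duration)) {
      phases[, irec] <- wrap_phase(2 * (psi + sqeta * (rec_t[irec] - t)) + pi)
      irec <- irec + 1L
    }
    if (t_next > duration) { t <- duration; break }
    psi <- psi + sqeta * dt_ev
    t <- t_next
    # spike of neuron j (lowest index wins ties via which.min); pulses may
    # carry late-phase receivers across threshold, so spikes are processed
    # as an avalanche in index order
    queue <- j
    while (length(queue)) {
      jj <- queue[1]; queue <- queue[-1]
      spk_t <- c(spk_t, t); spk_i <- c(spk_i, jj)
      psi[jj] <- -pi / 2
      kij <- K[, jj]
      idx <- which(kij != 0 & seq_len(n) != jj)
      if (length(idx)) {
        pm <- pulse_map(psi[idx], kij[idx], sqeta[idx])
        psi[idx] <- pm$psi
        fired <- idx[pm$fired]
        fired <- setdiff(fired, queue)
        if (length(fired)) queue <- c(queue, sort(fired))
      }
    }
  }
  list(time = rec_t[seq_len(irec - 1L)],
       phases = phases[, seq_len(irec - 1L), drop = FALSE],
       spikes = data.frame(t = spk_t, neuron = spk_i))
}

#' Averaged (phase-coupled) simulation of the network
#'
#' Integrates the period-averaged form of the pulse-coupled dynamics: each
#' presynaptic neuron contributes its (synaptically filtered) phase shift
#' once per period, smeared into a continuous drift,
#' \deqn{\dot\theta_i = \Omega_i + \frac{1}{T_i}\sum_j
#'   g_f(\theta_i - \theta_j;\, k_{ij}, \Omega_i, \tau_c).}
#' This averaged flow carries the locked states analysed by
#' [phase_locked_states()] and [sync_mode_eigenvalue()]; unlike the pure
#' delta-pulse event dynamics (whose common Mobius structure makes locking
#' only neutrally stable and blocks asymptotic synchronisation from generic
#' initial conditions) it converges exponentially.
#'
#' @inheritParams simulate_phase_network
#' @param dt integration step (ms).
#' @return list with `time`, `phases` (n x samples), `dt`.
#' @export
simulate_phase_coupled <- function(network, duration, init = NULL,
                                   seed = 1L, dt = 0.5, record_dt = 1) {
  stopifnot(inherits(network, "phase_network"))
  n <- network$n
  if (is.null(init)) init <- with_seed(seed, stats::runif(n, 0, 2 * pi))
  theta <- wrap_phase(init)
  Om <- network$Omega
  K <- network$coupling
  rate_fac <- Om / (2 * pi)        # 1/T_i
  Kmat <- K; diag(Kmat) <- 0
  OmM <- matrix(Om, n, n)          # receiver frequency per row
  tau_c <- network$tau_c
  f <- function(th) {
    D <- outer(th, th, "-")
    G <- filtered_prc(D, Kmat, OmM, tau_c)
    G[Kmat == 0] <- 0
    Om + rate_fac * rowSums(G)
  }
  nstep <- ceiling(duration / dt)
  stride <- max(1L, round(record_dt / dt))
  nrec <- floor(nstep / stride) + 1L
  out <- matrix(NA_real_, n, nrec)
  times <- numeric(nrec)
  out[, 1] <- theta
  irec <- 1L
  for (s in seq_len(nstep)) {
    k1 <- f(theta)
    k2 <- f(theta + dt / 2 * k1)
    k3 <- f(theta + dt / 2 * k2)
    k4 <- f(theta + dt * k3)
    theta <- wrap_phase(theta + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    if (s %% stride == 0L) {
      irec <- irec + 1L
      out[, irec] <- theta
      times[irec] <- s * dt
    }
  }
  list(time = times[seq_len(irec)], phases = out[, seq_len(irec),
                                                 drop = FALSE], dt = dt)
}

#' Kuramoto order parameter
#'
#' Magnitude and mean angle of the complex mean of the unit phasors.
#'
#' @param phases numeric vector of phases (radians).
#' @return list with `r` (in `[0, 1]`) and `psi` (mean angle).
#' @export
order_parameter <- function(phases) {
  z <- mean(exp(1i * phases))
  list(r = Mod(z), psi = Arg(z))
}

#' @rdname order_parameter
#' @param sim result of [simulate_phase_network()].
#' @return for the series variant: data frame with `t` and `r`.
#' @export
order_parameter_series <- function(sim) {
  data.frame(t = sim$time,
             r = apply(sim$phases, 2, function(p) order_parameter(p)$r))
}

# ---------------------------------------------------------------------------
# Synchronous-mode stability
# ---------------------------------------------------------------------------

#' Linearised deviation map of the synchronous mode
#'
#' Around the fully synchronised state, per-period deviations `delta_i` of
#' the spike times evolve (to linear order in the PRC slope `s` at the
#' locked arrival phase) as `delta' = M delta` with
#' `M = I - s * (n * I - 1 1^T)`.  The uniform direction is neutral (a
#' global time shift); the remaining `n - 1` directions share the single
#' distinct eigenvalue `lambda = 1 - n * s`, which determines stability
#' (`|lambda| < 1`).
#'
#' @param slope PRC slope at the locked arrival phase, in the lag
#'   convention (positive = a lagging neuron is advanced extra), for the
#'   pairwise coupling actually in use.
#' @param coupling optional extra scale factor applied to `slope` (use the
#'   default 1 when `slope` already includes the coupling).
#' @param n number of oscillators.
#' @return for `sync_mode_eigenvalue`: list with `lambda`, `stable`,
#'   `neutral`; for `sync_mode_matrix`: the n x n map matrix.
#' @export
sync_mode_eigenvalue <- function(slope, coupling = 1, n) {
  s <- slope * coupling
  lambda <- 1 - n * s
  list(lambda = lambda, stable = abs(lambda) < 1, neutral = s == 0)
}

#' @rdname sync_mode_eigenvalue
#' @export
sync_mode_matrix <- function(slope, coupling = 1, n) {
  s <- slope * coupling
  diag(n) - s * (n * diag(n) - matrix(1, n, n))
}

#' Synchronous-mode stability across coupling strengths
#'
#' For an all-to-all network with pairwise pulse weight `coupling / n`,
#' evaluates the filtered-interaction slope at the synchronous locked phase
#' (zero lag) and the resulting deviation-map eigenvalue: contraction for
#' positive coupling, expansion for negative, neutral at zero.
#'
#' @param couplings vector of total coupling strengths.
#' @param Omega common angular frequency.
#' @param n network size.
#' @param tau_c synaptic kernel timescale (ms).
#' @return data frame with `coupling`, `slope`, `lambda`, `stable`.
#' @export
sync_stability_scan <- function(couplings, Omega = 2 * pi / 20, n = 50,
                                tau_c = 2) {
  rows <- lapply(couplings, function(kap) {
    # lag convention: s = -dg_f/dphi at the locked phase 0 (shift per
    # radian of lag, once per period from each presynaptic neuron)
    s <- -filtered_prc_slope(0, kap / n, Omega, tau_c)
    ev <- sync_mode_eigenvalue(s, 1, n)
    data.frame(coupling = kap, slope = s, lambda = ev$lambda,
               stable = ev$stable)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Two-neuron phase locking
# ---------------------------------------------------------------------------

#' Phase difference flow of two reciprocally coupled oscillators
#'
#' Averaged flow of the relative phase `x = theta_2 - theta_1`:
#' \deqn{F(x) = \Omega_2 - \Omega_1
#'   + \frac{1}{T_2} g_f(x;\ k_{21}, \Omega_2, \tau_c)
#'   - \frac{1}{T_1} g_f(-x;\ k_{12}, \Omega_1, \tau_c)}
#' (neuron 2 is shifted by pulses from 1 arriving at its phase `x`, and
#' vice versa).
#'
#' @param network a two-neuron [phase_network()].
#' @param x relative phase(s), radians.
#' @return dx/dt (rad/ms).
#' @export
pair_difference_flow <- function(network, x) {
  stopifnot(inherits(network, "phase_network"), network$n == 2)
  Om <- network$Omega
  K <- network$coupling
  tc <- network$tau_c
  Om[2] - Om[1] +
    (Om[2] / (2 * pi)) * filtered_prc(x, K[2, 1], Om[2], tc) -
    (Om[1] / (2 * pi)) * filtered_prc(-x, K[1, 2], Om[1], tc)
}

#' Phase-locked states of two reciprocally coupled oscillators
#'
#' Locked states are the zeros of the relative-phase flow
#' ([pair_difference_flow()]) on `[0, 2*pi)`, located by a dense scan with
#' bisection.  The stability eigenvalue is the per-mean-period multiplier
#' of the spike-time map, `lambda = exp(F'(x*) * T)`; a state is stable iff
#' `|lambda| < 1`.  With zero coupling and equal frequencies every offset
#' is neutrally locked and the result is flagged `degenerate`.
#'
#' @param network a two-neuron [phase_network()].
#' @param grid_n scan resolution (default 512).
#' @return list with `states` (data frame: relative phase `x`, equivalent
#'   spike-time offset `chi` in ms, `lambda`, `stable`) and `degenerate`.
#' @export
phase_locked_states <- function(network, grid_n = 512) {
  stopifnot(inherits(network, "phase_network"), network$n == 2)
  Tbar <- mean(2 * pi / network$Omega)
  xs <- seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)]
  Fv <- pair_difference_flow(network, xs)
  if (max(abs(Fv)) < 1e-12) {
    return(list(states = data.frame(x = numeric(0), chi = numeric(0),
                                    lambda = numeric(0),
                                    stable = logical(0)),
                degenerate = TRUE))
  }
  states <- list()
  h <- 2 * pi / grid_n / 20
  for (i in seq_len(grid_n)) {
    x0 <- xs[i]; x1 <- if (i < grid_n) xs[i + 1] else 2 * pi
    f0 <- Fv[i]; f1 <- if (i < grid_n) Fv[i + 1]
                       else pair_difference_flow(network, 2 * pi)
    root <- if (f0 == 0) x0
            else if (f0 * f1 < 0) {
              stats::uniroot(function(x) pair_difference_flow(network, x),
                             c(x0, x1), tol = 1e-12)$root
            } else NA_real_
    if (is.finite(root)) {
      slope <- (pair_difference_flow(network, root + h) -
                  pair_difference_flow(network, root - h)) / (2 * h)
      lam <- exp(slope * Tbar)
      states[[length(states) + 1]] <-
        data.frame(x = root %% (2 * pi),
                   chi = (root %% (2 * pi)) / (2 * pi) * Tbar,
                   lambda = lam, stable = abs(lam) < 1)
    }
  }
  states <- if (length(states)) unique(do.call(rbind, states))
            else data.frame(x = numeric(0), chi = numeric(0),
                            lambda = numeric(0), stable = logical(0))
  list(states = states, degenerate = FALSE)
}

#' Relative spike timing of two units
#'
#' For each spike of the second unit, its offset to the most recent spike
#' of the first, normalised by the running period of the first unit
#' (offset modulo the period).
#'
#' @param t1,t2 spike-time vectors (ms) of the two units.
#' @return data frame with `t` (spike time of unit 2), `offset` (ms) and
#'   `rel` (offset as a fraction of the local period, in `[0, 1)`).
#' @export
relative_phase_series <- function(t1, t2) {
  if (length(t1) < 2 || length(t2) < 1) {
    return(data.frame(t = numeric(0), offset = numeric(0),
                      rel = numeric(0)))
  }
  isi <- diff(t1)
  out <- lapply(t2, function(ts) {
    i <- findInterval(ts, t1)
    if (i < 1 || i > length(isi)) return(NULL)
    off <- ts - t1[i]
    data.frame(t = ts, offset = off, rel = (off / isi[i]) %% 1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(t = numeric(0), offset = numeric(0),
                               rel = numeric(0)) else out
}
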