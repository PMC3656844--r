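# Single-neuron phase model: a theta-neuron-style oscillator
#
#   dtheta/dt = (1 - cos theta) + (1 + cos theta) * eta
#
# where eta is the effective drive (units rad^2/ms^2).  Under the
# half-angle substitution u = tan(theta/2) this is the Riccati equation
# du/dt = u^2 + eta, so for eta > 0 the neuron fires periodically and the
# period is available in closed form; for eta <= 0 the phase comes to rest
# (the radicand convention: the square root of a negative drive is taken
# as zero, the period is infinite and the rate zero).

# Phase value at which a threshold crossing counts as a spike.  theta is
# kept in [0, 2*pi); the flow is continuous through the spike so no state
# discontinuity is applied to theta itself.
THETA_SPIKE <- pi

# Default strength of the synaptic-drive increment per spike (dimensionless
# jump applied to omega).  A package default: chosen so that at the working
# input levels the drive variable integrates several spikes per synaptic
# time constant while individual spikes remain visible.
K_DEFAULT <- 0.5

#' Closed-form period of the theta-style oscillator
#'
#' For constant effective drive `eta` the phase equation
#' \eqn{\dot\theta = (1-\cos\theta) + (1+\cos\theta)\,\eta} has period
#' \eqn{T = \pi/\sqrt{\eta}} (integrate \eqn{d\theta/\dot\theta} over one
#' cycle with the substitution \eqn{u=\tan(\theta/2)}).  When the radicand
#' `eta` is not positive the square root is taken as zero by convention and
#' the period is infinite.
#'
#' @param eta effective drive (squared angular frequency, rad^2/ms^2);
#'   vectorised.
#' @return period in ms (`Inf` where `eta <= 0`).
#' @seealso [firing_rate()]
#' @export
#' @examples
#' closed_form_period(1)      # pi ms
#' closed_form_period(-0.5)   # Inf: subthreshold, no spiking
closed_form_period <- function(eta) {
  stopifnot(is.numeric(eta))
  ifelse(eta > 0, pi / sqrt(pmax(eta, 0)), Inf)
}

#' Firing rate of the theta-style oscillator
#'
#' Reciprocal of [closed_form_period()]: \eqn{r = \sqrt{\eta}/\pi} for
#' positive drive, zero otherwise.  Monotone nondecreasing in the drive.
#'
#' @inheritParams closed_form_period
#' @return firing rate in spikes/ms.
#' @export
firing_rate <- function(eta) {
  stopifnot(is.numeric(eta))
  sqrt(pmax(eta, 0)) / pi
}

#' Phase derivative of the network (spiking model, smooth part)
#'
#' Right-hand side of the phase equation of every neuron:
#' \deqn{\dot\theta_i = [(1-\cos\theta_i) +
#'   (1+\cos\theta_i)(I_i + \sum_j c_{ij}\omega_j)]/\tau_\theta}
#' The coupling enters the drive as a weighted sum over the presynaptic
#' synaptic-drive variables \eqn{\omega_j}, with `c[i, j]` the weight from
#' neuron `j` to neuron `i` (row = postsynaptic).  Self-coupling is carried
#' by the diagonal.
#'
#' @param theta numeric vector of phases (rad).
#' @param omega numeric vector of synaptic-drive variables.
#' @param params a [network_params()] object.
#' @param input per-neuron external drive at the current time (numeric
#'   vector, recycled if scalar).
#' @return vector of phase derivatives (rad/ms).
#' @export
theta_rhs <- function(theta, omega, params, input = 0) {
  stopifnot(inherits(params, "network_params"))
  n <- params$n
  if (length(theta) != n || length(omega) != n) {
    stop("state dimension does not match params$n = ", n, call. = FALSE)
  }
  input <- rep_len(input, n)
  drive <- input + as.vector(params$coupling %*% omega)
  ((1 - cos(theta)) + (1 + cos(theta)) * drive) / params$theta_timescale
}

#' Synaptic-drive derivative (smooth part) and spike increment
#'
#' Between spikes each drive variable relaxes exponentially,
#' \eqn{\dot\omega_i = -\omega_i/\tau_s}.  A spike of neuron `i` applies an
#' instantaneous increment `k` to \eqn{\omega_i} (the delta pulse of the
#' drive equation integrated across the event); `omega_rhs` returns the
#' smooth part plus the increments implied by `spikes_in_step`.
#'
#' @param omega numeric vector of drive variables.
#' @param params a [network_params()] object.
#' @param spikes_in_step integer vector of neuron indices that spiked
#'   within the current step (possibly empty); each occurrence contributes
#'   a jump `k / dt` to the returned derivative when `dt` is given, or is
#'   reported separately via the `"jump"` attribute when `dt` is `NULL`.
#' @param dt step size used to convert instantaneous jumps into an average
#'   derivative, or `NULL` (default) to return only the smooth part with
#'   the jump vector attached as an attribute.
#' @return vector of derivatives; with `dt = NULL` the attribute `"jump"`
#'   holds the instantaneous increment vector.
#' @export
omega_rhs <- function(omega, params, spikes_in_step = integer(0), dt = NULL) {
  stopifnot(inherits(params, "network_params"))
  n <- params$n
  if (length(omega) != n) {
    stop("state dimension does not match params$n = ", n, call. = FALSE)
  }
  smooth <- -omega / params$tau_s
  jump <- numeric(n)
  if (length(spikes_in_step)) {
    tab <- tabulate(spikes_in_step, nbins = n)
    jump <- params$k * tab  # recycles per-neuron k
  }
  if (is.null(dt)) {
    attr(smooth, "jump") <- jump
    smooth
  } else {
    smooth + jump / dt
  }
}

# Wrap phases into [0, 2*pi).
wrap_phase <- function(theta) theta %% (2 * pi)
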