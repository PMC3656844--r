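# Canonical parameter sets.
#
# The package's reference experiments: coupling matrices and inputs chosen
# once so that the two-node rate networks realise the four flow classes,
# the three-node family traverses the multistable -> limit-cycle
# bifurcation as its cyclic asymmetry grows, the two-oscillator timing
# networks realise the three spike-timing regimes, and the four-mode
# skeleton composes three of the flows in one circuit.

#' Canonical two-node networks for the four flow classes
#'
#' Symmetry parameters `(s, c, a, d)` (see [two_node_matrix()]) and inputs
#' of the reference two-node networks:
#' \describe{
#'   \item{fixed-point}{weak symmetric coupling; a single global attractor.}
#'   \item{limit-cycle}{self-excitation on node 1 with asymmetric
#'     cross-coupling (1 excites 2, 2 inhibits 1): a relaxation-style
#'     rotation.}
#'   \item{bistable}{symmetric mutual inhibition with self-excitation:
#'     winner-take-all.}
#'   \item{monostable}{asymmetric winner-take-all in which the second well
#'     is destroyed: one attractor with a nearby separatrix, suprathreshold
#'     kicks ride a large transient.}
#' }
#'
#' @param kind one of `"fixed-point"`, `"limit-cycle"`, `"bistable"`,
#'   `"monostable"`.
#' @return list with `coupling` (2x2 matrix), `input` (length-2 vector),
#'   `k`, `decomposition` (the `(s, c, a, d)` parameters) and `label` (the
#'   expected [classify_flow()] classification).
#' @export
canonical_two_node <- function(kind = c("fixed-point", "limit-cycle",
                                        "bistable", "monostable")) {
  kind <- match.arg(kind)
  par <- switch(kind,
    "fixed-point" = list(s = 0.1,  c = 0.1, a = 0,     d = 0,
                         input = c(0.5, 0.5),  label = "FIXED_POINT"),
    "limit-cycle" = list(s = -0.1, c = 0.4, a = -0.85, d = 0.6,
                         input = c(1.4, 0.15), label = "LIMIT_CYCLE"),
    "bistable"    = list(s = -1,   c = 0.3, a = 0,     d = 0,
                         input = c(0.5, 0.5),  label = "BISTABLE"),
    "monostable"  = list(s = -0.7, c = 0.8, a = 1.3,   d = -0.8,
                         input = c(0.4, 3.2),  label = "MONOSTABLE"))
  list(coupling = two_node_matrix(par$s, par$c, par$a, par$d),
       input = par$input, k = K_DEFAULT,
       decomposition = par[c("s", "c", "a", "d")], label = par$label)
}

#' Canonical three-node cyclic family
#'
#' Reference parameters of the simplified three-node system: inhibition
#' strength 1, self-coupling 0.5, common input 1.  At `alpha = 0` the
#' system has three multistable states; the reduced phase flow loses its
#' fixed points near `alpha ~ 0.27` (the full system near 0.5), and at
#' `alpha = 1` the flow is a limit cycle.
#'
#' @param alpha cyclic asymmetry.
#' @param beta further (non-cyclic) asymmetry; the reference monostable
#'   parameters are `alpha = 0.3`, `beta = 0.6`.
#' @return a simplified [rate_system()].
#' @export
canonical_three_node <- function(alpha = 0, beta = 0) {
  C <- if (beta == 0) heteroclinic_matrix(s = 1, alpha = alpha, self = 0.5)
       else further_asymmetry_matrix(s = 1, alpha = alpha, beta = beta,
                                     self = 0.5)
  rate_system(C, input = 1, simplified = TRUE)
}

#' Canonical synchronisation experiment
#'
#' All-to-all network of identical oscillators (period 20 ms) with total
#' coupling `coupling` split evenly across the `n - 1` afferents of each
#' neuron; the reference coupling values are `+0.5` (synchronising), `0`
#' (neutral) and `-0.5` (dispersing).
#'
#' @param coupling total coupling strength.
#' @param n network size (default 50).
#' @param period common period (ms).
#' @return a [phase_network()].
#' @export
canonical_sync_network <- function(coupling = 0.5, n = 50, period = 20) {
  Om <- 2 * pi / period
  K <- matrix(coupling / n, n, n); diag(K) <- 0
  phase_network(rep(Om, n), K)
}

#' Canonical two-oscillator spike-timing networks
#'
#' Reciprocally coupled identical oscillators (period 20 ms) in the three
#' timing regimes: `"synchrony"` (symmetric positive coupling; the in-phase
#' state is the attractor), `"drift"` (strong coupling asymmetry: no locked
#' state, the relative phase oscillates slowly through the cycle), and
#' `"monostable"` (asymmetry just below the saddle-node: one weakly stable
#' locked state with a nearby separatrix).
#'
#' @param regime one of `"synchrony"`, `"drift"`, `"monostable"`.
#' @param period common period (ms).
#' @return a two-neuron [phase_network()].
#' @export
canonical_timing_network <- function(regime = c("synchrony", "drift",
                                                "monostable"),
                                     period = 20) {
  regime <- match.arg(regime)
  Om <- 2 * pi / period
  kap <- switch(regime,
    "synchrony"  = c(0.1, 0.1),     # k12 (2 -> 1), k21 (1 -> 2)
    "drift"      = c(0.02, 0.18),
    "monostable" = c(0.045, 0.155))
  phase_network(c(Om, Om), matrix(c(0, kap[2], kap[1], 0), 2, 2))
}

#' Canonical four-mode connectivity skeleton
#'
#' Mode-level coupling of the multifunctional circuit, distributed across
#' 25 spiking neurons (counts 7, 6, 6, 6).  The active sub-networks realise
#' three flows: modes 1-2 (others inhibited) are a mutually inhibiting
#' bistable pair; modes 1-2-3 are monostable (mode 3, excited by mode 2,
#' is a transient suppressor that destroys mode 2's well, leaving mode 1 as
#' the single attractor); modes 1-3-4 form a cyclic disinhibition ring
#' producing a limit cycle.
#'
#' @param counts per-mode neuron counts.
#' @return a [mode_skeleton()].
#' @export
canonical_skeleton <- function(counts = c(7L, 6L, 6L, 6L)) {
  S <- matrix(c(
    #  from 1   2     3     4      (to:)
        0.3,  -1.0, -2.0,  0.0,   # 1
       -1.0,   0.3, -2.0,  0.0,   # 2
        0.0,   1.0,  0.3, -2.0,   # 3
       -4.0,  -4.0,  0.0,  0.5    # 4
  ), 4, 4, byrow = TRUE)
  mode_skeleton(S, counts)
}

#' Canonical per-mode input levels for each composed flow
#'
#' @param flow one of `"limit-cycle"`, `"bistable"`, `"monostable"`.
#' @param inhibit input level applied to the suppressed modes (strong
#'   enough that no mode can be re-excited through the coupling).
#' @return numeric vector of four per-mode levels.
#' @export
canonical_mode_levels <- function(flow = c("limit-cycle", "bistable",
                                           "monostable"),
                                  inhibit = -8) {
  flow <- match.arg(flow)
  switch(flow,
    "limit-cycle" = c(1, inhibit, 1, 1),
    "bistable"    = c(0.5, 0.5, inhibit, inhibit),
    "monostable"  = c(1.2, 0.4, -0.5, inhibit))
}

#' Canonical gating schedule of the composed experiment
#'
#' A limit-cycle flow from 0 ms, switched to the bistable flow at 500 ms (a
#' brief selection cue in the first 80 ms pins mode 2 as the initial
#' winner); with `pulses = TRUE` perturbation pulses at 700 ms and 1000 ms
#' flip the dominant mode to 1 and back to 2.  At 1100 ms the monostable
#' flow is selected: its attractor is mode 1, so the switch itself plays
#' out as a transient through the suppressor mode; a late perturbation at
#' 1650 ms kicks the network off its fixed point.  Total 1800 ms; the
#' sliding-window subspace analysis is conventionally applied to the flow
#' sequence up to 1600 ms (the late perturbation probes excitability and is
#' kept outside that epoch).
#'
#' @param pulse_amp amplitude of the perturbation pulses.
#' @param pulses include the perturbation pulses (set `FALSE` for the bare
#'   flow sequence, used when only the scheduled switches should register
#'   in the transition statistic).
#' @return a [gating_schedule()].
#' @export
canonical_schedule <- function(pulse_amp = 12, pulses = TRUE) {
  lc <- canonical_mode_levels("limit-cycle")
  bi <- canonical_mode_levels("bistable")
  mo <- canonical_mode_levels("monostable")
  cue <- c(-8, 4, bi[3], bi[4])
  segments <- data.frame(
    t0 = c(0, 500, 580, 1100), t1 = c(500, 580, 1100, 1800),
    level_1 = c(lc[1], cue[1], bi[1], mo[1]),
    level_2 = c(lc[2], cue[2], bi[2], mo[2]),
    level_3 = c(lc[3], cue[3], bi[3], mo[3]),
    level_4 = c(lc[4], cue[4], bi[4], mo[4]))
  pl <- if (pulses) {
    data.frame(
      t = c(700, 1000, 1650),
      duration = c(30, 20, 20),
      mode = c(1L, 2L, 2L),
      amplitude = pulse_amp)
  } else NULL
  gating_schedule(segments, pl)
}
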