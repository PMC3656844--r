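---
title: "Structured flows from symmetry breaking in spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured flows from symmetry breaking in spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfmnet)
```

# The scientific question

Behavioural and cognitive variables are routinely modelled as flows in two-
or three-dimensional state spaces, built from a small repertoire of
invariant elements: stable fixed points, limit cycles, bistable pairs of
attractors, and monostable (excitable) arrangements in which one fixed
point sits next to a separatrix so that suprathreshold perturbations ride a
large transient before returning. Neural activity, on the other hand, lives
in the very high-dimensional state space of a spiking network. `sfmnet`
implements a concrete bridge between the two: *symmetric* coupling makes a
network collapse quickly onto a low-dimensional attractive manifold (a
coherent mode), and *breaking the symmetry of the coupling matrix* sculpts
a slow, structured flow on that manifold. The same mechanism operates in
two complementary observables — the firing rate and the spike timing — and
several such flows can be composed in one circuit whose momentary flow is
selected by slow gating inputs.

# The spiking model

Each neuron carries a phase $\theta_i \in [0, 2\pi)$ and a synaptic-drive
variable $\omega_i$:

$$
\dot\theta_i = (1-\cos\theta_i) +
  (1+\cos\theta_i)\Big(I_i(t) + \sum_j c_{ij}\,\omega_j\Big), \qquad
\dot\omega_i = -\frac{\omega_i}{\tau_s} + k \sum_{t^*_i} \delta(t - t^*_i).
$$

A spike is the upward crossing of $\theta_i$ through $\pi$ (the flow is
continuous through the threshold; `simulate_network()` locates the crossing
by linear interpolation inside a fixed 0.05 ms step). Each spike of neuron
$i$ increments its own drive variable by $k$, so $\omega_i$ is a low-pass
filtered image of the neuron's firing rate with timescale $\tau_s$; the
coupling feeds the *presynaptic* drive variables, weighted by
$c_{ij}$ (row = postsynaptic), into the phase equation of the receiver.
With constant effective drive $\eta$ the phase equation has the closed-form
period $T = \pi/\sqrt{\eta}$ (substitute $u = \tan(\theta/2)$, which turns
the flow into the Riccati equation $\dot u = u^2 + \eta$); a non-positive
radicand means an infinite period and zero rate, a convention applied
throughout (`closed_form_period()`, `firing_rate()`).

Parameter defaults: $\tau_s = 20$ ms and a phase timescale of one, and
$k = 0.5$ per spike. The value of $k$ is a package default, chosen so that
at the working drive levels a neuron integrates several of its own spikes
per synaptic time constant (the rate description is meaningful) while
individual spikes remain visible in $\omega$. Time is in milliseconds
everywhere; $\omega$ carries units of squared angular frequency so that
rate $\propto \sqrt{\omega}$ is consistent with the period formula.

Delta-pulse coupling rules out generic adaptive ODE solvers, so the
integrator is a hand-written fixed-step classical Runge–Kutta scheme with
within-step interpolation of threshold crossings; interspike intervals of
an uncoupled neuron converge to the closed-form period at first order or
better in the step, with relative error below $10^{-3}$ at
$\mathrm{d}t = 0.01$ ms. Reruns with the same seed are bit-identical.

# Firing-rate reduction

When $\omega$ is slow compared to the firing, each spike train can be
replaced by its mean rate $\sqrt{\max(0, \text{drive})}/\pi$, giving the
closed rate system implemented by `rate_system()`/`rate_rhs()`:

$$
\dot\omega_i = -\frac{\omega_i}{\tau_s} +
  \frac{k}{\pi}\sqrt{\Big(I_i + \sum_j c_{ij}\omega_j\Big)_+}.
$$

A *simplified* variant drops the square root while keeping the
rectification, $\dot\omega_i = (-\omega_i + (\cdot)_+)/\tau_s$; it
reproduces the same qualitative flows in the working regime and is the
form used for the three-node phase reduction, where the analytics are
cleanest.

**Mode formation.** Under homogeneous coupling $c_{ij} = c$ every node
obeys the same nullcline equation, so the coherent mode
$\omega_i = \omega^*$ solves $\omega^* = g\sqrt{nc\,\omega^* + I}$ with
$g = k\tau_s/\pi$ (positive root only; `mode_fixed_point()`). The Jacobian
at that point is a diagonal relaxation plus a rank-one coupling term, so
its spectrum is $n-1$ degenerate eigenvalues at $-1/\tau_s$ plus one
distinguished eigenvalue
$\lambda = -1/\tau_s + knc/(2\pi\sqrt{nc\,\omega^*+I})$
(`mode_eigenvalue()`, verified against the dense finite-difference
Jacobian to $10^{-6}$ over a coupling grid). In this formulation the
mode-amplitude eigenvalue grows more negative for inhibitory coupling and
saturates at $-1/(2\tau_s)$ for strong excitation; dispersion of the
steady-state drives under normally distributed constant inputs shrinks
monotonically as the (positive) coupling grows, because the square-root
rate map flattens with the total drive. The input dispersion used in that
experiment ($\sigma = 0.3$ around a mean of 1) is a package choice.

**Two-node flows.** Any 2×2 coupling matrix decomposes into inter-neuron
strength $s$, self-coupling $c$, inter-neuron difference $a$ and
self-coupling difference $d$ (`two_node_matrix()`,
`decompose_two_node()`); $a$ and $d$ are the antisymmetric — symmetry
breaking — components. The four reference parameter sets
(`canonical_two_node()`) realise the four flow classes:

| flow | $(s, c, a, d)$ | inputs |
|---|---|---|
| fixed point | $(0.1, 0.1, 0, 0)$ | $(0.5, 0.5)$ |
| limit cycle | $(-0.1, 0.4, -0.85, 0.6)$ | $(1.4, 0.15)$ |
| bistable | $(-1, 0.3, 0, 0)$ | $(0.5, 0.5)$ |
| monostable | $(-0.7, 0.8, 1.3, -0.8)$ | $(0.4, 3.2)$ |

These numbers are package-defined reference conditions, chosen once so
that each topology is realised robustly at the model defaults: the
bistable set is a symmetric winner-take-all; the limit cycle is a
relaxation-style rotation between a self-exciting node and an
inhibitory partner; the monostable set is a winner-take-all whose second
well has been destroyed by the antisymmetric component, leaving one
attractor with a nearby separatrix. `classify_flow()` labels a system by
multi-start root finding (damped Newton from a grid, analytic Jacobian),
linear stability, an oscillation probe (transient of $10\tau_s$
discarded; peak-to-peak amplitude above $10^{-3}$ of the box and a
repeating autocorrelation), and a perturbation protocol: kicks of 1% and
50% of the attractor scale in the compass directions. A single stable
state whose large kick rides an excursion beyond 1.8 times the kick before
returning is monostable. The 1.8 threshold is a calibration of the
classifier: across the reference systems, stable-focus overshoot stays
below ≈1.4 while separatrix-crossing transients exceed ≈2.3. The same
flows appear in the full spiking network with the same matrices
(`classify_flow_spiking()` applies the trajectory-level version of the
protocol to smoothed drive traces; its probe states are deliberately
asymmetric, because an exactly symmetric winner-take-all state can be
stabilised by alternating spiking even where the rate system is unstable).

**Nullclines and polynomial portraits.** `nullclines()` extracts the
zero-level sets on a grid; `fit_polynomial_nullclines()` fits each curve
as a polynomial graph inside a window of interest. The rectified branches
along the axes are not graphs of a function and are cropped away by the
window; within it, the fitted and source nullclines intersect the same
number of times for all four reference systems — the flows are
qualitatively identical in polynomial form.

**Quality of the rate reduction.** `surrogate_drive()` rebuilds the drive
variable under a mean-rate flow, an equal-interspike-interval train, or a
Poisson train of the same rate, and `reduction_error()` scores the log
summed squared difference. Relative to the drive's own level the mean-rate
reduction tracks high-rate trains better than low-rate ones (the per-spike
jump is a smaller fraction of the running level); the absolute error is
rate-insensitive because the jump size $k$ is fixed.

# The three-node family and its phase reduction

`heteroclinic_matrix(s, alpha, self)` is the fully coupled three-node
motif: self-coupling 0.5, mutual inhibition $s = 1$, and a cyclic
asymmetry $\pm\alpha$ circulating around the ring — the most basic
connectivity with a rotational (heteroclinic-like) flow. At $\alpha = 0$
the simplified rate system is a three-state winner-take-all; the package's
reference conditions use a common input of 1.

The reduction to one phase variable (`reduce_to_phase()`) projects the
state onto the right singular vectors of the antisymmetric part of the
coupling (`svd_projection()`): for the cyclic family the zero-singular
direction is the diagonal $(1,1,1)/\sqrt3$ (the normal), and the two
in-plane directions span the mode plane. Writing the in-plane components
in polar coordinates, the radius and the normal coordinate are replaced by
their phase averages — computed numerically on a 512-point grid with a
two-dimensional Newton solve of $\langle\dot\rho\rangle = 0$,
$\langle\dot z\rangle = 0$, rather than by transcribing the unwieldy
closed-form polynomial coefficients — leaving a scalar $2\pi$-periodic
flow $\dot\varphi(\varphi)$. Its zeros are found by sign-change bracketing
and bisection (`phase_fixed_points()`), and `bifurcation_scan()` bisects
the family parameter to $10^{-4}$ for the smallest asymmetry at which all
zeros vanish.

At $\alpha = 0$ the reduced flow is driftless with three stable and three
unstable zeros whose angles match the projected fixed points of the full
three-dimensional system to better than 0.05 rad. The reduced flow loses
its fixed points at $\alpha_c \approx 0.27$; the full simplified system
holds on to its three states until $\alpha \approx 0.5$ (the averaged ring
is an approximation, so the two critical values differ — the *structure*
multistable-below/cycle-above is shared), and at $\alpha = 1$ both are
pure rotations. A further antisymmetric perturbation $\beta$ applied to
the 2→3 and 3→1 connection pairs (`further_asymmetry_matrix()`) breaks
the three-fold symmetry in favour of node 1; at the reference values
$\alpha = 0.3$, $\beta = 0.6$ the reduced flow has exactly one stable and
one unstable zero — monostable, with the separatrix nearby — and the full
system has a single stable state whose large-kick excursions ride toward
the ghosts of the destroyed states before returning.

As a planar reference for this repertoire, `excitator_rhs()` implements a
two-dimensional excitable system of the FitzHugh–Nagumo class (cubic local
dynamics, linear recovery; `excitator_params()` gives parameter sets for
the monostable, bistable and limit-cycle regimes), classified by the same
protocol.

# Spike-timing flows

On short timescales the drive variables are frozen and each neuron is a
bare oscillator of angular frequency $\Omega_i$ perturbed by presynaptic
spikes (`phase_network()`). The pulse convention is that a spike of weight
$\kappa$ multiplies the *rate-of-rise* term:
$\dot\theta = (1-\cos\theta)(1 + \kappa\,\delta(t)) + (1+\cos\theta)\eta$.
In the half-angle chart this is the exact map $u \mapsto u/(1-\kappa u)$,
giving the closed-form phase response curve of `analytic_prc()`: zero at
the spike and at mid-cycle, bimodal, with the stronger lobe on the late
side for excitation (and a strong enough excitatory pulse carries a
late-phase receiver across threshold — absorption). The alternative
convention, pulses on the input term, yields a unimodal near-symmetric
response under which excitatory coupling *cannot* synchronise this class
of oscillator — the package adopts the rate-of-rise convention because it
produces the synchronisation phenomenology the model is meant to exhibit.
`numerical_prc()` measures the same curve independently, by integrating
the phase equation with the pulse realised as a narrow rectangular
modulation and reading the asymptotic spike-time shift ten cycles after
the perturbation; at the reference parameters (period 20 ms, coupling
$\pm 0.3$) the two agree to better than $10^{-2}$ rad on a 64-point grid.
Two caveats are inherent: the exact spike instant is excluded from the
grid (a pulse simultaneous with the spike is an ordering convention), and
an inhibitory modulation cannot be made arbitrarily narrow (the
rate-of-rise factor must stay nonnegative), which bounds the inhibitory
couplings for which the finite-width realisation approximates the delta
limit.

**Why the analyses use an averaged flow.** The exact delta-pulse dynamics
of identical oscillators evolves by *common Möbius maps* — the free
Riccati flow and the pulse map are both Möbius in $u$, and all receivers
get the same map — so cross-ratios of the states are conserved: full
synchrony is not asymptotically attracting from generic initial
conditions, and every two-neuron locked state is neutrally stable at
linear order. The event-driven simulator (`simulate_phase_network()`,
exact between events, simultaneous spikes processed in index order with
avalanche handling) exhibits exactly this. Locking and synchronisation are
therefore analysed in the period-averaged flow, where each presynaptic
neuron contributes its response shift once per period, smeared by a short
synaptic kernel ($\tau_c = 2$ ms by default): to linear order the
interaction is the closed form of `filtered_prc()`,
$g_f(\varphi) \propto 1 + (\cos\varphi - \Omega\tau_c\sin\varphi)/(1 +
\Omega^2\tau_c^2)$. The $\sin$ skew contributed by the kernel's lag is
what makes locked states exponentially (rather than neutrally) stable,
and its sign makes *positive* coupling synchronising.
`simulate_phase_coupled()` integrates this averaged flow.

**Synchronous mode.** Around full synchrony, per-period deviations obey
the map $M = I - s\,(nI - \mathbf{1}\mathbf{1}^\top)$, where $s$ is the
interaction slope at the locked phase (lag convention): one neutral
eigenvalue (a global time shift) and a single distinct value
$\lambda = 1 - ns$ of multiplicity $n-1$ deciding stability
($|\lambda| < 1$; `sync_mode_eigenvalue()`, `sync_mode_matrix()`). For the
all-to-all reference network (50 oscillators, period 20 ms, total coupling
$\pm 0.5$ split over afferents) the scan (`sync_stability_scan()`) crosses
from unstable to stable as the coupling crosses zero to positive, and
simulations agree: the order parameter (`order_parameter()`, magnitude of
the complex mean phasor) reaches 1 for positive coupling and collapses to
the splay value for negative coupling.

**Two-neuron locking.** For a reciprocal pair the relative phase
$x = \theta_2 - \theta_1$ obeys the scalar flow of
`pair_difference_flow()`; locked states are its zeros
(`phase_locked_states()`: 512-point scan plus bisection), with the
per-period multiplier $\lambda = e^{F'(x^*)\bar T}$ and stability
$|\lambda| < 1$. Asymmetric coupling gives the flow a saddle-node-on-circle
structure, which is precisely the spike-timing version of the flow
repertoire (`canonical_timing_network()`): symmetric positive coupling
locks in phase (synchrony); asymmetry beyond the saddle-node leaves no
zero and the relative phase drifts slowly through the cycle (the
relative-phase oscillation); just below the saddle-node one weakly stable
offset survives next to its separatrix, and a suprathreshold perturbation
sends the relative phase around a full cycle before it relocks
(monostable timing). Stability verdicts agree with long-run simulated
convergence across seeded random coupling draws. `relative_phase_series()`
reads the same organisation directly from spike trains.

# Composing flows in one circuit

`canonical_skeleton()` defines a four-mode coupling skeleton distributed
across 25 spiking neurons (counts 7, 6, 6, 6; `expand_skeleton()` divides
each weight by the presynaptic block size so the mode mean fields obey the
skeleton exactly). Modes 1–2 form a bistable pair; modes 1–2–3 are
monostable (mode 3, excited by mode 2, destroys mode 2's well and then
dies away, leaving mode 1); modes 1–3–4 form a cyclic disinhibition ring
producing a limit cycle. Which flow is active is selected by per-mode
gating inputs (`canonical_mode_levels()`): suppressed modes receive −8,
deep enough that no surge in the active modes can re-excite them through
the coupling.

The reference schedule (`canonical_schedule()`) plays the three flows in
sequence: limit cycle from 0 ms; at 500 ms the bistable flow, with a brief
selection cue (500–580 ms) that pins mode 2 as the initial winner — the
winner would otherwise depend on the cycle phase at the switch — and
perturbation pulses at 700 and 1000 ms that flip the dominant mode to 1
and back to 2; at 1100 ms the monostable flow, whose attractor is mode 1,
so the switch itself plays out as a transient through the suppressor mode;
and a late perturbation at 1650 ms that kicks the settled network into a
large transient. Pulse amplitudes, the cue, and the inhibition depth are
package defaults tuned once to realise this qualitative sequence.
`run_schedule()` runs the full spiking network under the schedule, with a
frozen ±15% per-neuron input heterogeneity and a ±50% ladder of per-neuron
spike increments (mean $k$) standing in for biological dispersion; both
also give every channel a distinct variance, which stabilises the
principal axes of the window analysis below.

**Transition statistic.** `sliding_pca()` slides a 160 ms window with
100 ms overlap along multichannel traces, extracts the first ten principal
eigenvectors per window, and scores consecutive windows with
`subspace_similarity()` — the summed squared entries of
$E_a^\top E_b - I$, zero for identical sign-fixed eigenvector sets. Two
numerical conventions make the series reproducible: eigenvector signs are
fixed by the largest-loading-positive rule, and each window's covariance
is regularised by a small deterministic decreasing diagonal ladder
(`var_floor`), which pins the orientation of directions that carry no real
variance instead of letting estimation noise rotate them freely.
`transition_statistic()` applies the analysis to the *received synaptic
currents* $C\omega$ over the flow-sequence epoch (0–1600 ms): the received
current is the synaptic current proper, and for an expanded skeleton it
lives exactly in the rank-4 column space of the coupling, so components
beyond the true rank are exact zeros rather than noise. On a stationary
surrogate the series is flat; on the composed run it rises at every
reorganisation of the active subspace.

A limitation worth stating plainly: the statistic is saturating and
order-sensitive, so *any* change of the active configuration — a scheduled
flow switch, a dominance flip within the bistable flow, or the trailing
edge of a transition leaving the window — produces peaks of comparable
magnitude. In this implementation the two dominance flips score slightly
higher (≈21) than the flow switches (≈18), and each switch is accompanied
by an exit-trail peak roughly one window length later; with the 20 ms
synaptic timescale setting the transition durations, no setting of the
schedule or the estimator that we explored ranks the two scheduled
switches strictly first. The transitions are nonetheless clearly marked:
every peak of the series corresponds to a scripted event, and the
switch-adjacent peaks fall within one or two window strides of 500 and
1100 ms. `first_component_trace()` confirms the mode interpretation: over
the composed run the scores on the global first principal eigenvector
follow mode 1's mean field, the mode that participates in all three flows.

# What the reference experiments do and do not show

All quantitative claims in this vignette are recomputed by the test suite
and by `scripts/acceptance.R`; none are stored numbers. The reference
conditions are synthetic: connectivity is set by hand, inputs are
piecewise constant, and the only randomness is in seeded initial
conditions and the frozen heterogeneity. Passing tests therefore show that
the mechanism — symmetry of coupling building modes, asymmetry sculpting
flows on them, gating composing the flows — behaves as described *in this
model class*; they say nothing about whether biological networks use the
mechanism, about robustness to intrinsic noise or synaptic delays (both
out of scope), or about parameter regimes far from the defaults. Known
numerical limitations: the spiking integrator's pulse timing is
first-order accurate within a step; inhibitory response-curve measurements
require finite-width pulses (see above); phase averaging assumes the
trajectory stays near the averaged ring, which degrades near the
bifurcation; and the transition statistic's peak ranking is qualitative,
as discussed.

# Worked example

```{r example, eval = FALSE}
# classify a two-node flow and its spiking realisation
cz <- canonical_two_node("monostable")
classify_flow(rate_system(cz$coupling, input = cz$input, k = cz$k),
              box = c(0, 8))
classify_flow_spiking(network_params(cz$coupling, k = cz$k), cz$input,
                      box = c(0, 8))

# the three-node bifurcation
basis <- svd_projection(decompose_symmetry(heteroclinic_matrix(1, 0.3))$A)
fam <- function(a) reduce_to_phase(canonical_three_node(a), basis = basis)
bifurcation_scan(fam, c(0, 1))$alpha_critical

# the composed circuit
net <- build_multifunctional()
sim <- run_schedule(net, canonical_schedule(), seed = 1)
ss <- transition_statistic(sim)
similarity_peaks(ss, 4)
```
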