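# Composition of flows: a multifunctional circuit of four neural modes
# distributed across a spiking network.  Slow control inputs inhibit the
# modes that do not take part in a given flow, reshaping the effective
# phase space; transitions between flows are detected by a sliding-window
# principal-component subspace-similarity statistic.

#' Gating schedule for a multi-mode network
#'
#' Piecewise-constant per-mode input levels plus rectangular perturbation
#' pulses.
#'
#' @param segments data frame with columns `t0`, `t1` and `level_<p>` for
#'   each mode (or a plain matrix of levels with attributes); segments must
#'   tile the simulation interval.
#' @param pulses optional data frame with columns `t`, `duration`, `mode`,
#'   `amplitude`.
#' @return object of class `gating_schedule`.
#' @export
gating_schedule <- function(segments, pulses = NULL) {
  stopifnot(is.data.frame(segments), all(c("t0", "t1") %in% names(segments)))
  lev_cols <- grep("^level_", names(segments), value = TRUE)
  if (!length(lev_cols)) stop("segments need level_<mode> columns",
                              call. = FALSE)
  if (any(segments$t1 <= segments$t0)) stop("empty segment", call. = FALSE)
  if (nrow(segments) > 1 &&
      any(abs(segments$t0[-1] - segments$t1[-nrow(segments)]) > 1e-9)) {
    stop("segments must be contiguous", call. = FALSE)
  }
  if (!is.null(pulses)) {
    stopifnot(all(c("t", "duration", "mode", "amplitude") %in% names(pulses)))
  }
  structure(list(segments = segments, pulses = pulses,
                 m = length(lev_cols),
                 t_end = max(segments$t1)),
            class = "gating_schedule")
}

#' Per-mode input level of a schedule at time t
#' @param schedule a [gating_schedule()].
#' @param t time (ms).
#' @return numeric vector of per-mode levels (pulses included).
#' @export
schedule_levels <- function(schedule, t) {
  seg <- schedule$segments
  i <- findInterval(t, seg$t0)
  i <- min(max(i, 1L), nrow(seg))
  lev <- as.numeric(seg[i, grep("^level_", names(seg))])
  if (!is.null(schedule$pulses)) {
    p <- schedule$pulses
    act <- t >= p$t & t < p$t + p$duration
    if (any(act)) {
      for (r in which(act)) lev[p$mode[r]] <- lev[p$mode[r]] + p$amplitude[r]
    }
  }
  lev
}

#' Build the multifunctional spiking network
#'
#' Expands a 4-mode skeleton across `sum(counts)` spiking neurons (see
#' [expand_skeleton()]).  The sub-networks of modes left active by the
#' gating inputs realise the different flows: modes 1-2 bistability, modes
#' 1-2-3 monostability, and modes 1-3-4 a limit cycle.
#'
#' @param skeleton a 4x4 [mode_skeleton()] (default
#'   [canonical_skeleton()]).
#' @param k,tau_s spiking-model constants; `k` is the mean per-spike drive
#'   increment.
#' @param k_spread relative spread of the per-neuron spike increments:
#'   within each mode the `k_i` form an evenly spaced ladder over
#'   `k * (1 -/+ k_spread)` (mean `k`).  The heterogeneity mimics the
#'   dispersion of synaptic strengths and gives every neuron's drive
#'   variable a distinct fluctuation variance, which stabilises the
#'   principal axes of the sliding-window subspace analysis; set 0 for
#'   identical neurons.
#' @return a [network_params()] object with the per-neuron `mode` labels
#'   attached as attribute `"mode"`.
#' @export
build_multifunctional <- function(skeleton = canonical_skeleton(),
                                  k = K_DEFAULT, tau_s = 20,
                                  k_spread = 0.5) {
  stopifnot(inherits(skeleton, "mode_skeleton"), skeleton$m == 4)
  C <- expand_skeleton(skeleton)
  modes <- attr(C, "mode")
  kvec <- unlist(lapply(skeleton$counts, function(m) {
    if (m == 1) k else k * seq(1 - k_spread, 1 + k_spread, length.out = m)
  }))
  p <- network_params(unclass(C), tau_s = tau_s, k = kvec)
  attr(p, "mode") <- modes
  p
}

#' Run a gated simulation of the multifunctional network
#'
#' Full spiking simulation under the per-mode input schedule; the per-mode
#' mean fields of the drive variables are attached.
#'
#' @param network output of [build_multifunctional()].
#' @param schedule a [gating_schedule()].
#' @param seed RNG seed (initial phases).
#' @param dt integration step (ms).
#' @param record_every sampling interval of the stored trajectory (ms).
#' @param input_jitter relative spread of the frozen per-neuron input
#'   heterogeneity: each neuron's positive drive is scaled by a fixed
#'   factor drawn uniformly from `1 +/- input_jitter` (seeded by
#'   `jitter_seed`).  The dispersion breaks the exact within-mode symmetry,
#'   giving every active channel a distinct variance (which pins down the
#'   principal axes of the sliding-window analysis); inhibitory levels are
#'   left untouched.
#' @param jitter_seed seed of the frozen heterogeneity.
#' @return the [simulate_network()] result, with `mode_omega` (m x samples
#'   matrix of mode mean fields) and `modes` added.
#' @export
run_schedule <- function(network, schedule, seed = 1L, dt = 0.05,
                         record_every = 1, input_jitter = 0.15,
                         jitter_seed = 99L) {
  modes <- attr(network, "mode")
  stopifnot(!is.null(modes), inherits(schedule, "gating_schedule"))
  n <- network$n
  jit <- with_seed(jitter_seed,
                   stats::runif(n, 1 - input_jitter, 1 + input_jitter))
  # per-neuron schedule on a grid fine enough for all segment and pulse
  # edges (1 ms)
  breaks <- sort(unique(c(schedule$segments$t0,
                          schedule$segments$t1,
                          if (!is.null(schedule$pulses))
                            c(schedule$pulses$t,
                              schedule$pulses$t + schedule$pulses$duration))))
  breaks <- breaks[breaks < schedule$t_end]
  vals <- t(vapply(breaks, function(t) {
    lev <- schedule_levels(schedule, t)[modes]
    ifelse(lev > 0, lev * jit, lev)
  }, numeric(length(modes))))
  inp <- input_schedule(breaks, vals)
  sim <- simulate_network(network, inp, init = NULL,
                          duration = schedule$t_end, dt = dt, seed = seed,
                          record_every = record_every)
  sim$mode_omega <- mode_means(sim$omega, modes)
  sim$modes <- modes
  sim
}

# ---------------------------------------------------------------------------
# Sliding-window principal-component subspace analysis
# ---------------------------------------------------------------------------

#' Similarity of two principal subspaces
#'
#' Sum of squared entries of `t(Ea) %*% Eb - I` over the leading
#' `n_components` columns: zero when the (sign-fixed) eigenvector sets
#' coincide, and growing as the active subspace rotates.
#'
#' @param Ea,Eb matrices with orthonormal columns (eigenvector sets).
#' @param n_components number of leading components compared.
#' @param tol orthonormality tolerance.
#' @return nonnegative scalar.
#' @export
subspace_similarity <- function(Ea, Eb, n_components = min(ncol(Ea),
                                                           ncol(Eb)),
                                tol = 1e-6) {
  Ea <- Ea[, seq_len(n_components), drop = FALSE]
  Eb <- Eb[, seq_len(n_components), drop = FALSE]
  for (E in list(Ea, Eb)) {
    if (max(abs(crossprod(E) - diag(ncol(E)))) > tol) {
      stop("eigenvector sets must have orthonormal columns", call. = FALSE)
    }
  }
  M <- crossprod(Ea, Eb) - diag(n_components)
  sum(M^2)
}

# Deterministic orthonormal completion: extend E to n_target columns by
# Gram-Schmidt of the coordinate axes (in index order) against the columns
# already present.
complete_basis <- function(E, n_target) {
  n <- nrow(E)
  j <- 1L
  while (ncol(E) < n_target && j <= n) {
    e <- numeric(n); e[j] <- 1
    r <- e - E %*% crossprod(E, e)
    nr <- sqrt(sum(r^2))
    if (nr > 1e-8) E <- cbind(E, as.numeric(r / nr))
    j <- j + 1L
  }
  unname(E)
}

#' Deterministic eigenvector sign convention
#'
#' Flips each column so its largest-magnitude loading is positive, removing
#' the solver's arbitrary sign choice before eigenvector sets are compared.
#'
#' @param E matrix of eigenvectors (columns).
#' @return the sign-fixed matrix.
#' @export
fix_signs <- function(E) {
  for (j in seq_len(ncol(E))) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  E
}

#' Sliding-window principal component analysis
#'
#' Splits the multivariate trace into overlapping windows, extracts the
#' leading principal eigenvectors of each window's covariance (signs fixed
#' by the largest-loading-positive convention), and scores consecutive
#' windows with [subspace_similarity()].  The statistic rises when the
#' network's active subspace rotates, i.e. at transitions between flows.
#'
#' @param x traces: matrix with one row per channel (e.g. `omega` of a
#'   simulation, sampled at 1 ms) or channels x time.
#' @param times sample times (ms); defaults to `0:(ncol(x)-1)`.
#' @param window window length (ms), default 160.
#' @param overlap overlap of consecutive windows (ms), default 100.
#' @param n_components eigenvectors retained per window, default 10.
#' @param var_floor scale (as a fraction of the largest leading standard
#'   deviation across windows) below which a component's orientation is
#'   regarded as estimation noise.  Each window's covariance is
#'   regularised by a deterministic decreasing diagonal ladder of this
#'   magnitude before the eigendecomposition: directions with real variance
#'   are untouched, while near-degenerate directions are pinned to a fixed
#'   axis ordering, so quiet windows do not inject random rotations into
#'   the similarity series.
#' @return object of class `subspace_series`: list with `centers` (ms),
#'   `vectors` (list of loading matrices), `similarity` (between
#'   consecutive windows; `NA` for the first).
#' @export
sliding_pca <- function(x, times = NULL, window = 160, overlap = 100,
                        n_components = 10, var_floor = 0.02) {
  if (window <= overlap) stop("window must exceed overlap", call. = FALSE)
  if (is.null(times)) times <- seq_len(ncol(x)) - 1
  stride <- window - overlap
  t0s <- seq(times[1], times[length(times)] - window, by = stride)
  if (!length(t0s)) stop("record shorter than one window", call. = FALSE)
  nch <- nrow(x)
  n_components <- min(n_components, nch)
  covs <- vector("list", length(t0s))
  for (i in seq_along(t0s)) {
    idx <- which(times >= t0s[i] & times < t0s[i] + window)
    seg <- t(x[, idx, drop = FALSE])
    covs[[i]] <- stats::cov(seg)
  }
  s_ref2 <- max(vapply(covs, function(C) max(diag(C)), numeric(1)))
  # deterministic regularisation ladder, decreasing with channel index
  ladder <- (var_floor^2 * s_ref2) * (2 - (seq_len(nch) - 1) / nch)
  vecs <- lapply(covs, function(C) {
    ev <- eigen(C + diag(ladder), symmetric = TRUE)
    fix_signs(ev$vectors[, seq_len(n_components), drop = FALSE])
  })
  sim <- c(NA_real_,
           vapply(seq_along(vecs)[-1], function(i) {
             nc <- min(ncol(vecs[[i - 1]]), ncol(vecs[[i]]))
             subspace_similarity(vecs[[i - 1]], vecs[[i]], nc)
           }, numeric(1)))
  structure(list(centers = t0s + window / 2, vectors = vecs,
                 similarity = sim, window = window, overlap = overlap,
                 stride = stride),
            class = "subspace_series")
}

#' @export
print.subspace_series <- function(x, ...) {
  cat("<subspace_series>", length(x$centers), "windows of", x$window,
      "ms (stride", x$stride, "ms)\n")
  invisible(x)
}

#' Received synaptic currents of a simulation
#'
#' The current each neuron receives through the coupling,
#' `coupling %*% omega`, per recorded sample.  These traces live exactly in
#' the column space of the coupling matrix (rank at most the number of
#' modes for an expanded skeleton), which makes them the natural input for
#' the sliding-window subspace analysis: components beyond the true rank
#' are exact zeros rather than noise.
#'
#' @param sim a [simulate_network()] result (with `params` attached).
#' @param params optional [network_params()] overriding `sim$params`.
#' @return matrix, one row per neuron.
#' @export
received_currents <- function(sim, params = NULL) {
  p <- if (is.null(params)) sim$params else params
  stopifnot(inherits(p, "network_params"))
  p$coupling %*% sim$omega
}

#' Transition statistic of a composed run
#'
#' Canonical subspace-similarity analysis of a [run_schedule()] result:
#' sliding-window principal components of the received synaptic currents
#' over the flow-sequence epoch, scored between consecutive windows.
#'
#' @param sim a [run_schedule()] result.
#' @param epoch analysis interval (ms), default `c(0, 1600)` (the flow
#'   sequence of [canonical_schedule()]).
#' @param ... passed to [sliding_pca()].
#' @return a `subspace_series`.
#' @export
transition_statistic <- function(sim, epoch = c(0, 1600), ...) {
  keep <- sim$time >= epoch[1] & sim$time <= epoch[2]
  cur <- received_currents(sim)[, keep, drop = FALSE]
  sliding_pca(cur, times = sim$time[keep], ...)
}

#' Projection onto the global first principal component
#'
#' @param x traces (channels x time).
#' @return numeric time series: scores on the first principal eigenvector
#'   of the whole record (sign fixed: largest loading positive).
#' @export
first_component_trace <- function(x) {
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  E <- fix_signs(pc$rotation[, 1, drop = FALSE])
  as.numeric(scale(t(x), center = TRUE, scale = FALSE) %*% E)
}

#' Locate the largest local maxima of a similarity series
#'
#' @param series a `subspace_series`.
#' @param k number of peaks to report.
#' @return data frame with `t` (window center, ms) and `value`, strongest
#'   first.
#' @export
similarity_peaks <- function(series, k = 2) {
  s <- series$similarity
  t <- series$centers
  n <- length(s)
  is_peak <- vapply(seq_len(n), function(i) {
    if (is.na(s[i])) return(FALSE)
    left <- if (i > 1 && !is.na(s[i - 1])) s[i - 1] else -Inf
    right <- if (i < n && !is.na(s[i + 1])) s[i + 1] else -Inf
    s[i] >= left && s[i] > right
  }, logical(1))
  pk <- data.frame(t = t[is_peak], value = s[is_peak])
  pk <- pk[order(-pk$value), , drop = FALSE]
  utils::head(pk, k)
}
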