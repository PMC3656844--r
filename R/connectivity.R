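# Connectivity constructors and the symmetric/antisymmetric decomposition.
# Orientation everywhere: C[i, j] is the weight from presynaptic neuron j
# to postsynaptic neuron i (row = postsynaptic).

#' Symmetric/antisymmetric decomposition of a coupling matrix
#'
#' Splits `C` into its symmetric part `S = (C + t(C))/2` and antisymmetric
#' part `A = (C - t(C))/2`, the exact linear projections; `S + A`
#' reconstructs `C` to machine precision.  The antisymmetric component is
#' the locus of symmetry breaking: it converts fast collapse onto a mode
#' into slow structured flow along it.
#'
#' @param C square numeric matrix.
#' @return list with elements `S` and `A`.
#' @export
decompose_symmetry <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("C must be square", call. = FALSE)
  list(S = (C + t(C)) / 2, A = (C - t(C)) / 2)
}

#' Two-node coupling matrix from its symmetry parameters
#'
#' Parameterises any 2x2 coupling matrix by the inter-neuron strength `s`,
#' self-coupling strength `c`, inter-neuron difference `a` (the
#' antisymmetric component) and self-coupling difference `d`:
#' \deqn{C = \begin{pmatrix} c + d & s + a \\ s - a & c - d \end{pmatrix}}
#' `a = d = 0` gives a symmetric matrix; [decompose_two_node()] inverts the
#' construction exactly.
#'
#' @param s,c,a,d symmetry parameters (numeric scalars).
#' @return 2x2 coupling matrix.
#' @export
two_node_matrix <- function(s, c = 0, a = 0, d = 0) {
  matrix(c(c + d, s - a,
           s + a, c - d), 2, 2)
}

#' @rdname two_node_matrix
#' @param C a 2x2 coupling matrix.
#' @return for `decompose_two_node`: list with `s`, `c`, `a`, `d`.
#' @export
decompose_two_node <- function(C) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == 2, ncol(C) == 2)
  list(s = (C[1, 2] + C[2, 1]) / 2,
       c = (C[1, 1] + C[2, 2]) / 2,
       a = (C[1, 2] - C[2, 1]) / 2,
       d = (C[1, 1] - C[2, 2]) / 2)
}

#' Fully coupled three-node matrix with cyclic asymmetry
#'
#' The most basic connectivity producing a heteroclinic-cycle-like flow:
#' three nodes with self-coupling `self`, mutual inhibition of strength
#' `s`, and a cyclic (circulant) asymmetry of degree `alpha` that biases
#' the inhibition around the cycle 1 -> 2 -> 3 -> 1:
#' \deqn{C = \begin{pmatrix} \sigma & -s-\alpha & -s+\alpha \\
#'   -s+\alpha & \sigma & -s-\alpha \\
#'   -s-\alpha & -s+\alpha & \sigma \end{pmatrix}}
#' `alpha = 0` gives a symmetric winner-take-all matrix (three multistable
#' states); increasing `alpha` slides the system through a bifurcation to a
#' rotational (limit-cycle) flow.  The antisymmetric part is the cyclic
#' circulant of magnitude `alpha`.
#'
#' @param s inhibition strength (default 1).
#' @param alpha degree of cyclic asymmetry.
#' @param self self-coupling strength (default 0.5).
#' @return 3x3 coupling matrix.
#' @export
heteroclinic_matrix <- function(s = 1, alpha = 0, self = 0.5) {
  m <- matrix(0, 3, 3)
  diag(m) <- self
  fwd <- rbind(c(2, 1), c(3, 2), c(1, 3))   # j -> i around the cycle
  bwd <- fwd[, 2:1]
  m[fwd] <- -s + alpha
  m[bwd] <- -s - alpha
  m
}

#' Three-node matrix with an additional, non-cyclic asymmetry
#'
#' Starts from [heteroclinic_matrix()] and adds a further antisymmetric
#' asymmetry `beta` to the 2 -> 3 and 3 -> 1 connection pairs, breaking the
#' three-fold rotational symmetry of the cyclic family in favour of node 1.
#' `beta = 0` reduces exactly to `heteroclinic_matrix(s, alpha, self)`.  At
#' suitable `(alpha, beta)` both the reduced phase flow and the full system
#' are monostable: a single stable state with a nearby separatrix.
#'
#' @inheritParams heteroclinic_matrix
#' @param beta additional asymmetry applied to the 2 -> 3 and 3 -> 1
#'   connection pairs.
#' @return 3x3 coupling matrix.
#' @export
further_asymmetry_matrix <- function(s = 1, alpha = 0, beta = 0, self = 0.5) {
  m <- heteroclinic_matrix(s, alpha, self)
  m[3, 2] <- m[3, 2] + beta   # disinhibit 2 -> 3: node 2 cannot hold
  m[2, 3] <- m[2, 3] - beta
  m[1, 3] <- m[1, 3] + beta   # disinhibit 3 -> 1: node 3 cannot hold
  m[3, 1] <- m[3, 1] - beta
  m
}

#' Mode-level connectivity skeleton
#'
#' @param coupling m x m mode-level coupling matrix.
#' @param counts per-mode neuron counts (positive integers); must be as
#'   long as the skeleton dimension.
#' @return object of class `mode_skeleton`.
#' @export
mode_skeleton <- function(coupling, counts) {
  coupling <- as.matrix(coupling)
  m <- nrow(coupling)
  if (ncol(coupling) != m) stop("skeleton must be square", call. = FALSE)
  counts <- as.integer(counts)
  if (length(counts) != m || any(counts < 1)) {
    stop("counts must give a positive neuron count per mode", call. = FALSE)
  }
  structure(list(coupling = coupling, counts = counts, m = m),
            class = "mode_skeleton")
}

#' Split a total neuron count across modes
#'
#' Equal counts with any remainder assigned to the leading modes.
#'
#' @param n_total total neuron count.
#' @param m number of modes.
#' @return integer vector of length `m` summing to `n_total`.
#' @export
split_counts <- function(n_total, m) {
  base <- n_total %/% m
  extra <- n_total %% m
  as.integer(base + (seq_len(m) <= extra))
}

#' Expand a mode skeleton to a neuron-level coupling matrix
#'
#' Every neuron of mode `p` receives from every neuron of mode `q` the
#' weight `skeleton[p, q] / counts[q]`; dividing by the presynaptic block
#' size makes the mode mean fields of the expanded network obey the
#' skeleton-level dynamics exactly (for identical within-mode states).
#'
#' @param skeleton a [mode_skeleton()].
#' @return n x n coupling matrix, `n = sum(counts)`, with the mode index of
#'   each neuron attached as attribute `"mode"`.
#' @export
expand_skeleton <- function(skeleton) {
  stopifnot(inherits(skeleton, "mode_skeleton"))
  counts <- skeleton$counts
  modes <- rep(seq_len(skeleton$m), counts)
  n <- sum(counts)
  C <- skeleton$coupling[modes, modes, drop = FALSE] /
    rep(counts[modes], each = n)
  dimnames(C) <- NULL
  attr(C, "mode") <- modes
  C
}

#' Mode mean fields of a trajectory
#'
#' @param x matrix with one row per neuron (e.g. the `omega` field of a
#'   [simulate_network()] result).
#' @param modes integer vector of per-neuron mode labels.
#' @return matrix with one row per mode: the within-mode means.
#' @export
mode_means <- function(x, modes) {
  do.call(rbind, lapply(sort(unique(modes)), function(p) {
    colMeans(x[modes == p, , drop = FALSE])
  }))
}

#' Read/write a coupling matrix as whitespace-delimited text
#'
#' Files carry an optional header comment `# rows=post cols=pre`
#' documenting the orientation.
#'
#' @param path file path.
#' @export
read_coupling <- function(path) {
  unname(as.matrix(utils::read.table(path, comment.char = "#")))
}

#' @rdname read_coupling
#' @param C coupling matrix to write.
#' @export
write_coupling <- function(C, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rows=post cols=pre", con)
  utils::write.table(format(C, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
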