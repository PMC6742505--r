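#' Unwrapping configuration
#'
#' The unwrapper estimates the integer wrap-count field k of a wrapped phase
#' volume by MAP inference on a six-neighbourhood pairwise MRF whose
#' potential is the weighted squared difference of the true phase between
#' neighbours. The magnitude image acts as a quality map: per-edge weights
#' are the geometric mean of the two voxels' magnitudes, each normalised by
#' the `magnitude_norm_percentile` percentile and clipped to \[0, 1\];
#' voxels whose normalised magnitude falls below `mask_threshold` are
#' excluded (weight 0).
#'
#' @param potential only `"squared"` (convex, hence every binary move is
#'   submodular and exactly solvable by one graph cut).
#' @param quality_weighting `"magnitude"` or `"none"`.
#' @param magnitude_norm_percentile percentile normalising the magnitude.
#' @param max_iterations cap on binary moves.
#' @param mask_threshold normalised-magnitude fraction below which voxels
#'   are masked out (`0 <= mask_threshold < 1`).
#' @return An object of class `unwrap_config`.
#' @export
unwrap_config <- function(potential = "squared",
                          quality_weighting = c("magnitude", "none"),
                          magnitude_norm_percentile = 95,
                          max_iterations = 100L,
                          mask_threshold = 0.05) {
  potential <- match.arg(potential)
  quality_weighting <- match.arg(quality_weighting)
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (mask_threshold < 0 || mask_threshold >= 1)
    stop("mask_threshold must be in [0, 1)")
  structure(list(potential = potential, quality_weighting = quality_weighting,
                 magnitude_norm_percentile = magnitude_norm_percentile,
                 max_iterations = as.integer(max_iterations),
                 mask_threshold = mask_threshold),
            class = "unwrap_config")
}

#' Quality weight of a neighbour pair
#'
#' Geometric mean of the two voxels' magnitudes, each normalised by the
#' configured percentile value and clipped to \[0, 1\]; 0 if either voxel
#' falls below the mask threshold. Monotone nondecreasing in both
#' magnitudes.
#'
#' @param mag_i,mag_j magnitudes (>= 0).
#' @param config an [unwrap_config()].
#' @param norm_value the percentile value used for normalisation (defaults
#'   to the larger input so a bare call saturates at 1).
#' @return Weights in \[0, 1\].
#' @export
pair_weight <- function(mag_i, mag_j, config = unwrap_config(),
                        norm_value = max(mag_i, mag_j)) {
  if (any(mag_i < 0) || any(mag_j < 0)) stop("magnitudes must be >= 0")
  qi <- pmin(mag_i / norm_value, 1)
  qj <- pmin(mag_j / norm_value, 1)
  w <- sqrt(qi * qj)
  w[qi < config$mask_threshold | qj < config$mask_threshold] <- 0
  w
}

# six-neighbourhood edge structure of a grid: for each axis, the linear
# indices of the lower and upper voxel of every adjacent pair
grid_edges <- function(dims) {
  strides <- c(1L, dims[1], dims[1] * dims[2])
  lapply(1:3, function(a) {
    keep_len <- dims
    keep_len[a] <- dims[a] - 1L
    co <- as.matrix(expand.grid(seq_len(keep_len[1]), seq_len(keep_len[2]),
                                seq_len(keep_len[3])))
    i1 <- 1L + (co[, 1] - 1L) + (co[, 2] - 1L) * strides[2] +
      (co[, 3] - 1L) * strides[3]
    list(i1 = as.integer(i1), i2 = as.integer(i1 + strides[a]))
  })
}

# normalised quality map and mask from a magnitude volume (or NULL)
quality_map <- function(magnitude, config, dims) {
  if (is.null(magnitude) || config$quality_weighting == "none") {
    q <- array(1, dims)
    if (!is.null(magnitude)) {
      mag <- as_volume_array(magnitude)
      p <- quantile(mag, config$magnitude_norm_percentile / 100, names = FALSE)
      mask <- (mag / p) >= config$mask_threshold
    } else mask <- array(TRUE, dims)
    return(list(q = q, mask = mask))
  }
  mag <- as_volume_array(magnitude)
  if (!all(dim(mag) == dims)) stop("magnitude grid differs from phase grid")
  p <- quantile(mag, config$magnitude_norm_percentile / 100, names = FALSE)
  if (p <= 0) stop("magnitude normalisation percentile is not positive")
  q <- pmin(mag / p, 1)
  mask <- q >= config$mask_threshold
  q[!mask] <- 0
  list(q = q, mask = mask)
}

# per-edge data for the move problems: indices, weights, wrapped differences
unwrap_edge_data <- function(phi, q, mask) {
  dims <- dim(phi)
  edges <- grid_edges(dims)
  i1 <- integer(0); i2 <- integer(0); w <- numeric(0); dphi <- numeric(0)
  for (e in edges) {
    we <- sqrt(q[e$i1] * q[e$i2])
    we[!mask[e$i1] | !mask[e$i2]] <- 0
    keep <- we > 0
    i1 <- c(i1, e$i1[keep]); i2 <- c(i2, e$i2[keep])
    w <- c(w, we[keep]); dphi <- c(dphi, phi[e$i1[keep]] - phi[e$i2[keep]])
  }
  list(i1 = i1, i2 = i2, w = w, dphi = dphi)
}

#' MRF energy of a wrap-count configuration
#'
#' `sum over 6-neighbour pairs of w * (2*pi*(k_i - k_j) + (phi_i - phi_j))^2`.
#' Invariant under adding a global integer constant to k.
#'
#' @param counts integer 3D array of wrap counts k.
#' @param wrapped wrapped `phase_volume`.
#' @param magnitude optional `magnitude_volume` for quality weighting.
#' @param config an [unwrap_config()].
#' @return Scalar energy.
#' @export
unwrap_energy <- function(counts, wrapped, magnitude = NULL,
                          config = unwrap_config()) {
  phi <- wrapped$data
  k <- as_volume_array(counts)
  if (!all(dim(k) == dim(phi))) stop("counts and phase shapes differ")
  qm <- quality_map(magnitude, config, dim(phi))
  ed <- unwrap_edge_data(phi, qm$q, qm$mask)
  t <- 2 * pi * (k[ed$i1] - k[ed$i2]) + ed$dphi
  sum(ed$w * t^2)
}

# build and solve one binary move problem; returns the move field and both
# energies. Internal core shared by binary_move() and unwrap().
solve_move <- function(k, ed, n) {
  t <- 2 * pi * (k[ed$i1] - k[ed$i2]) + ed$dphi
  e00 <- ed$w * t^2                      # = e11
  e10 <- ed$w * (t + 2 * pi)^2
  e01 <- ed$w * (t - 2 * pi)^2
  # elementary-graph reparameterisation, vectorised (terms are always
  # submodular here: e01 + e10 - 2 * e00 = 8 * pi^2 * w >= 0)
  gap <- e01 + e10 - 2 * e00
  a <- e10 - e00
  b <- e00 - e10                         # e11 - e10
  const <- sum(e00) + sum(pmin(a, 0)) + sum(pmin(b, 0))
  cs <- accum(n, ed$i1, pmax(a, 0)) + accum(n, ed$i2, pmax(b, 0))
  ct <- accum(n, ed$i1, pmax(-a, 0)) + accum(n, ed$i2, pmax(-b, 0))
  res <- cpp_maxflow(n, cs, ct, ed$i1, ed$i2, gap, numeric(length(gap)))
  list(delta = res$labels, energy_before = sum(ed$w * t^2),
       energy_after = res$flow + const,
       net = list(n_nodes = n, cap_source = cs, cap_sink = ct,
                  edge_i = ed$i1, edge_j = ed$i2, cap_ij = gap,
                  cap_ji = numeric(length(gap)), constant_offset = const),
       labels = res$labels, flow = res$flow)
}

#' One binary move of the iterative unwrapper
#'
#' Solves for the binary increment field delta minimising
#' `E(k + delta | phi_w)` by a single graph cut. The pairwise move energies
#' are `E(0,0) = E(1,1) = V(t)`, `E(1,0) = V(2*pi + t)`,
#' `E(0,1) = V(-2*pi + t)` with `t = 2*pi*(k_i - k_j) + (phi_i - phi_j)`;
#' convexity of V makes every such term submodular
#' (`V(2*pi+t) + V(-2*pi+t) - 2*V(t) = 8*pi^2` for the squared potential).
#'
#' @param counts integer 3D array of current wrap counts.
#' @param wrapped wrapped `phase_volume`.
#' @param magnitude optional `magnitude_volume`.
#' @param config an [unwrap_config()].
#' @return A list: `delta` (integer array), `energy_before`, `energy_after`.
#' @export
binary_move <- function(counts, wrapped, magnitude = NULL,
                        config = unwrap_config()) {
  phi <- wrapped$data
  k <- as_volume_array(counts)
  qm <- quality_map(magnitude, config, dim(phi))
  ed <- unwrap_edge_data(phi, qm$q, qm$mask)
  mv <- solve_move(k, ed, length(phi))
  delta <- array(mv$delta, dim(phi))
  if (mv$energy_after >= mv$energy_before - 1e-9) {
    delta[] <- 0L                        # optimum reached: null move
    mv$energy_after <- mv$energy_before
  }
  list(delta = delta, energy_before = mv$energy_before,
       energy_after = mv$energy_after)
}

#' Unwrap a phase volume by iterated binary graph cuts
#'
#' MAP estimation of the integer wrap counts under a six-neighbourhood MRF
#' with convex squared-difference potentials: starting from k = 0, each
#' iteration solves one binary move problem exactly by max-flow and
#' increments the counts where the move lowers the energy; the iteration
#' stops at the first move with no energy decrease (for convex potentials
#' this fixed point is the global minimum over integer count fields, up to
#' the global-offset gauge).
#'
#' @param wrapped wrapped `phase_volume` (values in (-pi, pi]).
#' @param magnitude optional `magnitude_volume` used as quality map.
#' @param config an [unwrap_config()].
#' @return An object of class `unwrap_result`: `counts` (integer array k),
#'   `unwrapped` (`phase_volume`, `phi_w + 2*pi*k`), `energy_trace`
#'   (initial energy then each accepted move's energy; strictly
#'   decreasing), `converged`, `final_move` (the last move problem's flow
#'   network, solution labels and flow -- the input to
#'   [unwrap_confidence()]), and `mask`.
#' @export
unwrap <- function(wrapped, magnitude = NULL, config = unwrap_config()) {
  stopifnot(inherits(wrapped, "phase_volume"))
  if (!wrapped$wrapped) stop("input phase volume is not flagged wrapped")
  phi <- wrapped$data
  dims <- dim(phi)
  qm <- quality_map(magnitude, config, dims)
  if (!any(qm$mask)) stop("all voxels are masked out")
  ed <- unwrap_edge_data(phi, qm$q, qm$mask)
  n <- length(phi)
  k <- array(0, dims)
  t0 <- 2 * pi * (k[ed$i1] - k[ed$i2]) + ed$dphi
  energy <- sum(ed$w * t0^2)
  trace <- energy
  converged <- FALSE
  final_move <- NULL
  for (it in seq_len(config$max_iterations)) {
    mv <- solve_move(k, ed, n)
    if (mv$energy_after < energy - 1e-9) {
      k <- k + array(mv$delta, dims)
      energy <- mv$energy_after
      trace <- c(trace, energy)
      final_move <- mv
    } else {
      converged <- TRUE
      final_move <- mv
      break
    }
  }
  counts <- array(as.integer(round(k)), dims)
  structure(list(
    counts = counts,
    unwrapped = phase_volume(phi + 2 * pi * counts, wrapped = FALSE,
                             voxel_size = wrapped$voxel_size),
    energy_trace = trace, converged = converged,
    final_move = final_move, mask = qm$mask, config = config,
    anchor = which.max(qm$q * qm$mask),
    dims = dims), class = "unwrap_result")
}

#' @export
print.unwrap_result <- function(x, ...) {
  cat(sprintf(paste0("<unwrap_result %s: %d move(s), energy %.6g -> %.6g, ",
                     "%sconverged, counts in [%d, %d]>\n"),
              paste(x$dims, collapse = "x"), length(x$energy_trace) - 1L,
              x$energy_trace[1], x$energy_trace[length(x$energy_trace)],
              if (x$converged) "" else "NOT ",
              min(x$counts), max(x$counts)))
  invisible(x)
}
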