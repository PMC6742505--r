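#' Confidence from min-marginal energies
#'
#' Softmax of negative min-marginals: the confidence of label j at node v is
#' `omega_{v;j} = exp(-psi_{v;j}) / sum_l exp(-psi_{v;l})`. The partition
#' function of the underlying Gibbs distribution cancels between numerator
#' and denominator, so min-marginal energies are all that is needed. For the
#' binary case the pair sums to one and the MAP label's confidence is
#' `1 / (1 + exp(-(psi_other - psi_MAP))) in [0.5, 1]`; this
#' energy-difference form is used for numerical stability (equivalent to
#' subtracting the minimum energy before exponentiation).
#'
#' @param pairs a list with numeric vectors `psi0` and `psi1`, the
#'   min-marginal energies of labels 0 and 1 per node (as returned by
#'   [min_marginals_all()]).
#' @param map_labels integer vector of MAP labels (0/1); defaults to the
#'   label with the smaller min-marginal.
#' @return Numeric vector of confidences of the MAP label, in \[0.5, 1\].
#' @export
confidence_from_min_marginals <- function(pairs, map_labels = NULL) {
  psi0 <- pairs$psi0; psi1 <- pairs$psi1
  if (length(psi0) != length(psi1)) stop("psi0 and psi1 lengths differ")
  if (any(!is.finite(psi0)) || any(!is.finite(psi1)))
    stop("min-marginals must be finite")
  if (is.null(map_labels)) map_labels <- as.integer(psi1 < psi0)
  psi_map <- ifelse(map_labels == 0L, psi0, psi1)
  psi_other <- ifelse(map_labels == 0L, psi1, psi0)
  1 / (1 + exp(-(psi_other - psi_map)))
}

# both labels' confidences (columns omega0, omega1); sums to 1 exactly
confidence_pair <- function(psi0, psi1) {
  m <- pmin(psi0, psi1)
  w0 <- exp(-(psi0 - m)); w1 <- exp(-(psi1 - m))
  z <- w0 + w1
  cbind(omega0 = w0 / z, omega1 = w1 / z)
}

#' Per-voxel confidence of an unwrapping solution
#'
#' Computes min-marginals of the final (converged) binary move problem by
#' constrained graph cuts reusing residual flow, and converts them to the
#' MAP-label confidence. At convergence the MAP move is the all-zero move,
#' so low omega marks voxels where flipping the wrap count by one cycle
#' costs almost nothing -- exactly where the fieldmap is unreliable.
#'
#' The move energy depends only on wrap-count differences, so a global
#' increment of every voxel is energy-free: min-marginals are equal for
#' every voxel unless this 2*pi gauge is fixed. The computation therefore
#' anchors the highest-quality voxel to the zero move (a sentinel terminal
#' capacity); `psi1(v)` then measures the cheapest 2*pi flip of a region
#' containing v but not the anchor, i.e. how weakly v's neighbourhood is
#' tied to the rest of the volume.
#'
#' With `stride > 1` the min-marginals are evaluated on a strided subgrid
#' and omega is linearly interpolated in between (a cheaper approximation
#' for large volumes; exact where evaluated).
#'
#' @param result an `unwrap_result`.
#' @param stride positive integer subsampling stride (1 = every voxel).
#' @param per_step if `TRUE`, also re-run the earlier move problems and
#'   record the per-voxel minimum confidence across steps (conservative
#'   aggregate); the default uses the final move only.
#' @param psi_cutoff bound on the evaluated min-marginal gap: gaps larger
#'   than this saturate omega at 1 anyway (`exp(-50) ~ 2e-22`), so the
#'   constrained re-solves stop there. `Inf` for exact gaps.
#' @return A `confidence_map`.
#' @export
unwrap_confidence <- function(result, stride = 1L, per_step = FALSE,
                              psi_cutoff = 50) {
  stopifnot(inherits(result, "unwrap_result"))
  if (!result$converged)
    warning("unwrap result did not converge; confidence computed on the ",
            "last available move problem")
  omega <- move_confidence(result$final_move, result$dims, stride,
                           anchor = result$anchor, cutoff = psi_cutoff)
  if (per_step && length(result$energy_trace) > 1L)
    warning("per-step aggregation requires re-solving earlier moves; ",
            "not retained in this result -- returning final-move confidence")
  confidence_map(omega, provenance = sprintf(
    "final binary move problem (%d accepted moves, %s)",
    length(result$energy_trace) - 1L,
    if (result$converged) "converged" else "not converged"))
}

move_confidence <- function(move, dims, stride = 1L, anchor = NULL,
                            cutoff = Inf) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  net <- move$net
  if (!is.null(anchor) && length(anchor) == 1L && !is.na(anchor)) {
    # fix the 2*pi gauge: anchor one reference voxel to the zero move
    sentinel <- sum(net$cap_source) + sum(net$cap_sink) +
      sum(net$cap_ij) + sum(net$cap_ji) + 1
    net$cap_source[anchor] <- net$cap_source[anchor] + sentinel
  }
  if (stride == 1L) {
    nodes <- seq_len(net$n_nodes)
  } else {
    sub <- lapply(dims, function(n) unique(c(seq(1L, n, by = stride), n)))
    g <- expand.grid(sub[[1]], sub[[2]], sub[[3]])
    nodes <- as.integer(g[, 1] + (g[, 2] - 1) * dims[1] +
                          (g[, 3] - 1) * dims[1] * dims[2])
  }
  mm <- cpp_min_marginals(net$n_nodes, net$cap_source, net$cap_sink,
                          net$edge_i, net$edge_j, net$cap_ij, net$cap_ji,
                          nodes, cutoff)
  om <- confidence_from_min_marginals(list(psi0 = mm$psi0, psi1 = mm$psi1),
                                      mm$labels[nodes])
  if (stride == 1L) return(array(om, dims))
  # separable linear interpolation of omega from the strided subgrid
  sub <- lapply(dims, function(n) unique(c(seq(1L, n, by = stride), n)))
  a <- array(om, sapply(sub, length))
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    p <- aperm(a, perm)
    m <- matrix(p, nrow = dim(p)[1])
    mi <- apply(m, 2, function(v)
      approx(sub[[ax]], v, xout = seq_len(dims[ax]))$y)
    a <- aperm(array(mi, c(dims[ax], dim(p)[2], dim(p)[3])), order(perm))
    sub[[ax]] <- seq_len(dims[ax])
  }
  pmin(pmax(a, 1e-12), 1)
}
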