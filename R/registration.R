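#' Registration configuration
#'
#' Discrete cubic-B-spline refinement of a phase-encode displacement field.
#' Control points move only along the PE axis over a discrete label set
#' `{-label_range, ..., +label_range}` in steps of `label_step` (halved at
#' each finer level). The data term is spatially encoded normalised mutual
#' information (SEMI): a per-control-point NMI computed from a joint
#' histogram with Parzen intensity windows and a Gaussian spatial weight of
#' sd `gamma_sd` (default: the control-point spacing) truncated at 3 sd.
#' The pairwise term penalises the absolute difference of the total
#' (accumulated + candidate) displacement of neighbouring control points,
#' weighted by `lambda_global` modulated by the projected unwrapping
#' confidence. Optimisation is alpha-expansion, coarse to fine.
#'
#' @param spacing control-point spacing in voxels at the finest level.
#' @param levels number of coarse-to-fine passes (spacing doubles per
#'   coarser level).
#' @param label_step displacement quantum in voxels at the coarsest level.
#' @param label_range maximum |displacement| label, voxels.
#' @param bins intensity histogram bins.
#' @param gamma_sd sd of the spatial Gaussian kernel, voxels (`NULL`: use
#'   the level's control-point spacing).
#' @param lambda_global global penalty weight lambda in (0, 1].
#' @param max_cycles maximum alpha-expansion sweeps per level.
#' @param parzen `"cubic"` (cubic B-spline Parzen windows) or `"nearest"`.
#' @param intensity_quantiles range of each image mapped onto the bins.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(spacing = 5, levels = 2L, label_step = 1,
                       label_range = 10, bins = 64L, gamma_sd = NULL,
                       lambda_global = 0.5, max_cycles = 5L,
                       parzen = c("cubic", "nearest"),
                       intensity_quantiles = c(0.01, 0.99)) {
  parzen <- match.arg(parzen)
  if (label_step <= 0) stop("label_step must be > 0")
  if (label_range < label_step) stop("label_range must be >= label_step")
  if (lambda_global <= 0 || lambda_global > 1)
    stop("lambda_global must be in (0, 1]")
  if (spacing < 1) stop("spacing must be >= 1 voxel")
  structure(list(spacing = spacing, levels = as.integer(levels),
                 label_step = label_step, label_range = label_range,
                 bins = as.integer(bins), gamma_sd = gamma_sd,
                 lambda_global = lambda_global,
                 max_cycles = as.integer(max_cycles), parzen = parzen,
                 intensity_quantiles = intensity_quantiles),
            class = "reg_config")
}

# cubic B-spline blending weights for fractional position u in [0, 1)
bspline_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# dense n x nc basis matrix of a 1D uniform cubic B-spline lattice with
# knot spacing h covering voxels 0..n-1; control point c sits at (c-2)*h
bspline_axis_matrix <- function(n, h) {
  x <- (seq_len(n) - 1) / h
  i0 <- floor(x)
  u <- x - i0
  nc <- floor((n - 1) / h) + 4
  B <- matrix(0, n, nc)
  W <- bspline_weights(u)
  for (l in 0:3) {
    cols <- i0 + l + 1
    B[cbind(seq_len(n), cols)] <- B[cbind(seq_len(n), cols)] + W[, l + 1]
  }
  B
}

#' Cubic B-spline control grid for PE-only deformation
#'
#' @param dims image dimensions (voxels).
#' @param spacing control-point spacing, voxels (scalar or per axis).
#' @param pe_axis phase-encode axis the coefficients displace along.
#' @return An object of class `bspline_grid` with zero coefficients.
#' @export
bspline_grid <- function(dims, spacing, pe_axis = 2L) {
  spacing <- rep_len(spacing, 3)
  if (any(spacing < 1)) stop("spacing must be >= 1 voxel")
  B <- lapply(1:3, function(a) bspline_axis_matrix(dims[a], spacing[a]))
  nc <- vapply(B, ncol, integer(1))
  structure(list(dims = as.integer(dims), spacing = spacing,
                 pe_axis = as.integer(pe_axis),
                 coeffs = array(0, nc), basis = B,
                 positions = lapply(1:3, function(a)
                   (seq_len(nc[a]) - 2) * spacing[a])),
            class = "bspline_grid")
}

# contract a 3D array with a matrix along one axis
contract_axis <- function(A, M, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(A, perm)
  m <- M %*% matrix(p, nrow = dim(p)[1])
  aperm(array(m, c(nrow(M), dim(p)[2], dim(p)[3])), order(perm))
}

#' Dense displacement field of a B-spline grid
#'
#' Tensor-product evaluation of the cubic B-spline coefficients on the
#' voxel grid. The basis is a partition of unity, so all-equal coefficients
#' reproduce that constant exactly.
#'
#' @param grid a [bspline_grid()].
#' @return A `displacement_field` on the image grid.
#' @export
dense_field <- function(grid) {
  stopifnot(inherits(grid, "bspline_grid"))
  f <- contract_axis(grid$coeffs, grid$basis[[1]], 1)
  f <- contract_axis(f, grid$basis[[2]], 2)
  f <- contract_axis(f, grid$basis[[3]], 3)
  displacement_field(f, pe_axis = grid$pe_axis)
}

# weighted projection of a voxel field onto the control grid: a convex
# combination with weights given by the (nonnegative) basis values
project_to_grid <- function(field, grid) {
  field <- as_volume_array(field)
  num <- field
  for (a in 1:3) num <- contract_axis(num, t(grid$basis[[a]]), a)
  den <- array(1, dim(field))
  for (a in 1:3) den <- contract_axis(den, t(grid$basis[[a]]), a)
  out <- num
  ok <- den > 1e-10
  out[ok] <- num[ok] / den[ok]
  out[!ok] <- 0
  list(values = out, active = ok)
}

#' Project a confidence map onto the control grid
#'
#' Per-control-point confidence sigma_i: the convex combination of the
#' voxel confidences under the control point's (normalised, nonnegative)
#' B-spline basis weights; in \[0, 1\].
#'
#' @param conf a `confidence_map` (or 3D array in \[0, 1\]).
#' @param grid a [bspline_grid()].
#' @return A 3D array over the control grid.
#' @export
project_confidence <- function(conf, grid) {
  stopifnot(inherits(grid, "bspline_grid"))
  omega <- as_volume_array(conf)
  if (!all(dim(omega) == grid$dims))
    stop("confidence map grid differs from the image grid")
  pmin(pmax(project_to_grid(omega, grid)$values, 0), 1)
}

#' Pairwise regularisation cost of two neighbouring control points
#'
#' Absolute difference of total (accumulated + candidate) displacements:
#' a full-course penalty on the deformation difference, not just on the
#' incremental update.
#'
#' @param chi_i,chi_j candidate displacement labels, voxels.
#' @param current_total_i,current_total_j accumulated displacements at the
#'   two control points, voxels.
#' @return Nonnegative cost (symmetric in i and j).
#' @export
pairwise_cost <- function(chi_i, chi_j, current_total_i = 0,
                          current_total_j = 0) {
  abs((current_total_i + chi_i) - (current_total_j + chi_j))
}

# map intensities to continuous bin coordinates in [0, bins-1]
to_bin_coords <- function(v, limits, bins) {
  if (limits[2] <= limits[1]) return(rep(0, length(v)))
  pmin(pmax((v - limits[1]) / (limits[2] - limits[1]), 0), 1) * (bins - 1)
}

intensity_limits <- function(img, config) {
  quantile(img, config$intensity_quantiles, names = FALSE)
}

# region box (per-axis index ranges) around control point cp, 3*sd wide
cp_region <- function(grid, cp, sd3) {
  pos <- vapply(1:3, function(a) grid$positions[[a]][cp[a]], numeric(1))
  lo <- pmax(1L, as.integer(ceiling(pos - sd3 + 1)))
  hi <- pmin(grid$dims, as.integer(floor(pos + sd3 + 1)))
  if (any(lo > hi)) return(NULL)
  list(ranges = Map(seq, lo, hi), pos = pos)
}

# Gaussian spatial weights over a region box
region_gamma <- function(box, sd) {
  rx <- box$ranges[[1]]; ry <- box$ranges[[2]]; rz <- box$ranges[[3]]
  dx2 <- (rx - 1 - box$pos[1])^2
  dy2 <- (ry - 1 - box$pos[2])^2
  dz2 <- (rz - 1 - box$pos[3])^2
  g <- outer(outer(dx2, dy2, "+"), dz2, "+")
  exp(-g / (2 * sd^2))
}

# sample `img` over a region box with the box's voxels displaced by
# `disp_box` along pe_axis (linear interpolation; zero outside the FOV),
# optionally Jacobian-modulated by the 1D derivative of disp along PE
sample_displaced <- function(img, box, disp_box, pe_axis,
                             modulate = TRUE) {
  dims <- dim(img)
  rx <- box$ranges[[1]]; ry <- box$ranges[[2]]; rz <- box$ranges[[3]]
  shp <- c(length(rx), length(ry), length(rz))
  X <- array(rep(rx, times = shp[2] * shp[3]), shp)
  Y <- array(rep(rep(ry, each = shp[1]), times = shp[3]), shp)
  Z <- array(rep(rz, each = shp[1] * shp[2]), shp)
  P <- switch(pe_axis, X, Y, Z) + disp_box
  n_pe <- dims[pe_axis]
  inside <- P >= 1 & P <= n_pe
  Pc <- pmin(pmax(P, 1), n_pe)
  i0 <- pmin(floor(Pc), n_pe - 1)
  fr <- Pc - i0
  lin <- function(px) {
    cx <- X; cy <- Y; cz <- Z
    if (pe_axis == 1) cx <- px else if (pe_axis == 2) cy <- px else cz <- px
    cx + (cy - 1) * dims[1] + (cz - 1) * dims[1] * dims[2]
  }
  val <- (1 - fr) * img[lin(i0)] + fr * img[lin(i0 + 1)]
  val[!inside] <- 0
  if (modulate) {
    jac <- array(1, shp)
    m <- shp[pe_axis]
    if (m >= 3) {
      perm <- c(pe_axis, setdiff(1:3, pe_axis))
      dpe <- aperm(disp_box, perm)
      j <- array(1, dim(dpe))
      j[2:(m - 1), , ] <- 1 + (dpe[3:m, , , drop = FALSE] -
                               dpe[1:(m - 2), , , drop = FALSE]) / 2
      j[1, , ] <- 1 + (dpe[2, , ] - dpe[1, , ])
      j[m, , ] <- 1 + (dpe[m, , ] - dpe[m - 1, , ])
      jac <- aperm(j, order(perm))
    }
    val <- val * pmax(jac, 0.05)
  }
  val
}

#' Spatially weighted local joint histogram at a control point
#'
#' Joint histogram of reference and floating intensities over the support
#' of the control point's Gaussian spatial kernel (truncated at 3 sd), with
#' Parzen intensity windows; the histogram's total mass equals the sum of
#' the spatial weights over the region.
#'
#' @param ref,flt 3D arrays on one grid.
#' @param control_point integer length-3 control-point index.
#' @param grid a [bspline_grid()].
#' @param config a [reg_config()].
#' @param gamma_sd override of the spatial kernel sd (voxels).
#' @return An object of class `local_histogram`: `H` (bins x bins), `mass`.
#' @export
semi_histogram <- function(ref, flt, control_point, grid,
                           config = reg_config(),
                           gamma_sd = NULL) {
  ref <- as_volume_array(ref); flt <- as_volume_array(flt)
  sd <- if (!is.null(gamma_sd)) gamma_sd
        else if (!is.null(config$gamma_sd)) config$gamma_sd
        else mean(grid$spacing)
  box <- cp_region(grid, control_point, 3 * sd)
  if (is.null(box)) stop("empty region for control point")
  g <- region_gamma(box, sd)
  rl <- intensity_limits(ref, config); fl <- intensity_limits(flt, config)
  rx <- box$ranges
  rsub <- ref[rx[[1]], rx[[2]], rx[[3]], drop = FALSE]
  fsub <- flt[rx[[1]], rx[[2]], rx[[3]], drop = FALSE]
  H <- cpp_parzen_hist(to_bin_coords(rsub, rl, config$bins),
                       to_bin_coords(fsub, fl, config$bins),
                       as.numeric(g), config$bins,
                       config$parzen == "cubic")
  structure(list(H = H, mass = sum(g)), class = "local_histogram")
}

# normalised mutual information (Studholme), natural log, from a joint
# histogram; a single-occupied-bin histogram is degenerate and scores 2
nmi_from_hist <- function(H, warn_degenerate = TRUE) {
  s <- sum(H)
  if (s <= 0) stop("empty histogram")
  p <- H / s
  hx <- -sum(ifelse(rowSums(p) > 0, rowSums(p) * log(rowSums(p)), 0))
  hy <- -sum(ifelse(colSums(p) > 0, colSums(p) * log(colSums(p)), 0))
  hxy <- -sum(ifelse(p > 0, p * log(p), 0))
  if (hxy <= 1e-12) {
    if (warn_degenerate)
      warning("degenerate (single-bin) local histogram; NMI defined as 2")
    return(2)
  }
  (hx + hy) / hxy
}

#' SEMI data score of a candidate control-point displacement
#'
#' Normalised mutual information of the local (spatially weighted) joint
#' histogram between the reference and the floating image resampled with
#' the control point's region displaced by `label` voxels along the PE
#' axis on top of the baseline field (the Gaussian weight confines the
#' candidate move to the control point's neighbourhood). Higher is better;
#' the identity bound is 2.
#'
#' @param ref,flt 3D arrays on one grid (ref undistorted, flt distorted).
#' @param grid a [bspline_grid()].
#' @param label candidate displacement, voxels.
#' @param config a [reg_config()].
#' @param control_point integer length-3 control-point index.
#' @param base_disp optional baseline displacement array (e.g. the fieldmap
#'   initialisation) added before the candidate move.
#' @return Scalar NMI score.
#' @export
semi_data_term <- function(ref, flt, grid, label, config = reg_config(),
                           control_point = NULL, base_disp = NULL) {
  ref <- as_volume_array(ref); flt <- as_volume_array(flt)
  if (is.null(control_point)) stop("control_point is required")
  if (abs(label) > config$label_range + 1e-9)
    stop("label outside the configured range")
  sd <- if (!is.null(config$gamma_sd)) config$gamma_sd else mean(grid$spacing)
  box <- cp_region(grid, control_point, 3 * sd)
  if (is.null(box)) stop("empty region for control point")
  rl <- intensity_limits(ref, config); fl <- intensity_limits(flt, config)
  scr <- semi_score(ref, flt, grid, control_point, label, config, sd,
                    box, rl, fl, base_disp)
  scr
}

# Core SEMI evaluation given precomputed box and intensity limits.
# A candidate label is scored as a *constant* displacement of the local
# region (the Gaussian weight localises it to the control point): scoring
# the basis-attenuated single-point move instead would under-shift the
# region by the tensor basis peak (~0.30) and bias the argmax upward.
semi_score <- function(ref, flt, grid, cp, label, config, sd, box, rl, fl,
                       base_disp = NULL) {
  rx <- box$ranges
  shp <- vapply(rx, length, integer(1))
  disp_box <- array(label, shp)
  if (!is.null(base_disp))
    disp_box <- disp_box + base_disp[rx[[1]], rx[[2]], rx[[3]], drop = FALSE]
  fs <- sample_displaced(flt, box, disp_box, grid$pe_axis, modulate = TRUE)
  rsub <- ref[rx[[1]], rx[[2]], rx[[3]], drop = FALSE]
  g <- region_gamma(box, sd)
  H <- cpp_parzen_hist(to_bin_coords(rsub, rl, config$bins),
                       to_bin_coords(fs, fl, config$bins),
                       as.numeric(g), config$bins,
                       config$parzen == "cubic")
  nmi_from_hist(H, warn_degenerate = FALSE)
}

#' Confidence-modulated discrete B-spline registration
#'
#' Refines a phase-encode displacement field by registering the distorted
#' floating image to the undistorted reference. The deformation is a cubic
#' B-spline field along the PE axis over a discrete label set, optimised by
#' alpha-expansion: each sweep lets every control point keep its label or
#' switch to the candidate, solved as one binary graph cut (non-submodular
#' pairwise instances have those edge weights set to zero, and a move is
#' only accepted if the true objective decreases, so the cost trace is
#' non-increasing). The data weight of control point i is
#' `1 - sigma_i * lambda` and the pairwise weight `sigma * lambda` (edge
#' sigma: mean of the two endpoints), so high unwrapping confidence freezes
#' the fieldmap solution and low confidence lets the image drive the
#' refinement. Coarse-to-fine: the control spacing halves and the field is
#' composed between levels.
#'
#' @param ref 3D array, undistorted reference (e.g. T1) on the EPI grid.
#' @param flt 3D array, distorted EPI.
#' @param init `displacement_field` initialisation (e.g. from the
#'   fieldmap), or `NULL` for zero.
#' @param conf `confidence_map` (or array), or `NULL` for sigma = 0 (with a
#'   warning): purely image-driven refinement.
#' @param config a [reg_config()].
#' @param pe_axis used when `init` is `NULL`.
#' @return A `displacement_field` (init + refinement) with attributes
#'   `energy_trace` (per-level list of objective values, non-increasing)
#'   and `refinement` (the B-spline part alone).
#' @export
register <- function(ref, flt, init = NULL, conf = NULL,
                     config = reg_config(), pe_axis = 2L) {
  ref <- as_volume_array(ref); flt <- as_volume_array(flt)
  dims <- dim(ref)
  if (!all(dim(flt) == dims)) stop("reference and floating grids differ")
  if (!is.null(init)) {
    stopifnot(inherits(init, "displacement_field"))
    if (!all(dim(init$data) == dims)) stop("init field grid differs")
    pe_axis <- init$pe_axis
    init_data <- init$data
  } else init_data <- array(0, dims)
  if (is.null(conf)) {
    warning("no confidence map supplied; using sigma = 0 ",
            "(unmodulated, image-driven refinement)")
    omega <- array(0, dims)
  } else omega <- as_volume_array(conf)
  if (!all(dim(omega) == dims)) stop("confidence map grid differs")

  rl <- intensity_limits(ref, config); fl <- intensity_limits(flt, config)
  refine <- array(0, dims)
  traces <- vector("list", config$levels)

  for (lev in seq_len(config$levels)) {
    h <- config$spacing * 2^(config$levels - lev)
    step <- config$label_step / 2^(lev - 1)
    labels <- sort(unique(c(0, seq(-config$label_range, config$label_range,
                                   by = step))))
    grid <- bspline_grid(dims, h, pe_axis)
    sd <- if (!is.null(config$gamma_sd)) config$gamma_sd else h
    nc <- dim(grid$coeffs)
    proj <- project_to_grid(refine, grid)
    Rcp <- proj$values
    sigma <- pmin(pmax(project_to_grid(omega, grid)$values, 0), 1)
    slam <- pmin(pmax(sigma * config$lambda_global, 0), 1)
    base_disp <- init_data + refine

    # active control points: those whose kernel region meets the image
    cps <- as.matrix(expand.grid(seq_len(nc[1]), seq_len(nc[2]),
                                 seq_len(nc[3])))
    boxes <- lapply(seq_len(nrow(cps)), function(r)
      cp_region(grid, cps[r, ], 3 * sd))
    active <- which(!vapply(boxes, is.null, logical(1)) & proj$active)
    n_act <- length(active)
    if (n_act == 0) { traces[[lev]] <- numeric(0); next }

    # data table: SEMI score of every active control point x label
    D <- matrix(0, n_act, length(labels))
    for (a in seq_len(n_act)) {
      r <- active[a]
      for (l in seq_along(labels))
        D[a, l] <- semi_score(ref, flt, grid, cps[r, ], labels[l], config,
                              sd, boxes[[r]], rl, fl, base_disp)
    }

    # 6-neighbour edges between active control points
    aidx <- array(0L, nc); aidx[active] <- seq_len(n_act)
    epairs <- do.call(rbind, lapply(1:3, function(ax) {
      sh <- nc; sh[ax] <- nc[ax] - 1L
      if (any(sh < 1)) return(NULL)
      co <- as.matrix(expand.grid(seq_len(sh[1]), seq_len(sh[2]),
                                  seq_len(sh[3])))
      co2 <- co; co2[, ax] <- co2[, ax] + 1L
      cbind(aidx[co], aidx[co2])
    }))
    epairs <- epairs[epairs[, 1] > 0 & epairs[, 2] > 0, , drop = FALSE]

    wdata <- 1 - slam[active]
    Ra <- Rcp[active]
    sl_e <- (slam[active][epairs[, 1]] + slam[active][epairs[, 2]]) / 2

    state <- rep(which(labels == 0), n_act)
    energy_of <- function(st) {
      u <- -sum(wdata * D[cbind(seq_len(n_act), st)])
      tot <- Ra + labels[st]
      u + sum(sl_e * abs(tot[epairs[, 1]] - tot[epairs[, 2]]))
    }
    E <- energy_of(state)
    trace <- E
    for (cycle in seq_len(config$max_cycles)) {
      changed <- FALSE
      for (al in seq_along(labels)) {
        cost0 <- -wdata * D[cbind(seq_len(n_act), state)]
        cost1 <- -wdata * D[, al]
        t0i <- Ra[epairs[, 1]] + labels[state[epairs[, 1]]]
        t0j <- Ra[epairs[, 2]] + labels[state[epairs[, 2]]]
        t1i <- Ra[epairs[, 1]] + labels[al]
        t1j <- Ra[epairs[, 2]] + labels[al]
        e00 <- sl_e * abs(t0i - t0j); e01 <- sl_e * abs(t0i - t1j)
        e10 <- sl_e * abs(t1i - t0j); e11 <- sl_e * abs(t1i - t1j)
        keep <- (e00 + e11) <= (e01 + e10) + 1e-12
        net <- flow_network(n_act)
        net <- add_unary(net, seq_len(n_act), cost0, cost1)
        if (any(keep))
          net <- add_pairwise(net, epairs[keep, 1], epairs[keep, 2],
                              e00[keep], e01[keep], e10[keep], e11[keep],
                              tol = 1e-9)
        cut <- max_flow(net)
        prop <- state
        prop[cut$labels == 1L] <- al
        Ep <- energy_of(prop)
        if (Ep < E - 1e-9) {
          state <- prop; E <- Ep; changed <- TRUE
          trace <- c(trace, E)
        }
      }
      if (!changed) break
    }
    traces[[lev]] <- trace
    grid$coeffs[active] <- labels[state]
    refine <- refine + dense_field(grid)$data
  }

  out <- displacement_field(init_data + refine, pe_axis = pe_axis,
                            pe_sign = if (!is.null(init)) init$pe_sign else 1L)
  attr(out, "energy_trace") <- traces
  attr(out, "refinement") <- refine
  out
}
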