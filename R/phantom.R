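#' Synthetic phase-phantom specification
#'
#' Parameterises a brain-like synthetic dataset: a smooth background phase
#' surface (low-order 3D polynomial in coordinates normalised to \[-1, 1\])
#' spanning several 2*pi cycles, Gaussian phase bumps, an optional
#' resection-like region producing locally steep field variation with a
#' low-magnitude core, and an ellipsoidal head mask. The default grid is
#' 64 x 64 x 32 voxels of 2.5 x 2.5 x 2.7 mm, the resolution of a typical
#' interventional EPI acquisition.
#'
#' The generated true phase is smooth: adjacent (6-neighbour) absolute
#' differences stay below pi inside the mask provided
#' `rim_amplitude <= 4 * rim_width` (the rim ridge's maximum slope is about
#' `0.61 * rim_amplitude / rim_width` radians per voxel), which makes
#' wrapping the only source of discontinuity in the noise-free wrapped
#' image.
#'
#' @param grid_shape voxels per axis (all >= 8).
#' @param voxel_size mm per axis (all > 0).
#' @param background_poly_coeffs named coefficients of the background
#'   polynomial phase surface, radians, over terms
#'   `const, x, y, z, xx, yy, zz, xy, xz, yz` in normalised coordinates.
#' @param blob_params list of Gaussian bumps, each
#'   `list(centre = voxel, sd = voxels, amplitude = radians)`.
#' @param resection `NULL`, or `list(centre, radii, rim_amplitude,
#'   rim_width)`: an ellipsoidal cavity (voxel units) with a steep radial
#'   Gaussian phase ridge on its rim and a low-magnitude core.
#' @param mask_radius ellipsoid radii of the head mask, voxels.
#' @param seed integer RNG seed used by stochastic phantom outputs.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         voxel_size = c(2.5, 2.5, 2.7),
                         background_poly_coeffs = c(
                           const = 0, x = 4, y = 3, z = 2,
                           xx = 3, yy = -2.5, zz = 2,
                           xy = 1.5, xz = 0, yz = 1),
                         blob_params = list(
                           list(centre = c(24, 40, 12), sd = 6, amplitude = 2.5),
                           list(centre = c(44, 24, 20), sd = 8, amplitude = -3)),
                         resection = list(centre = c(42, 22, 16),
                                          radii = c(9, 8, 6),
                                          rim_amplitude = 2, rim_width = 2.5),
                         mask_radius = c(28, 28, 14),
                         seed = 0L) {
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("invalid phantom_spec field 'grid_shape': all axes must be >= 8")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("invalid phantom_spec field 'voxel_size': must be > 0")
  cn <- c("const", "x", "y", "z", "xx", "yy", "zz", "xy", "xz", "yz")
  coeffs <- numeric(10); names(coeffs) <- cn
  if (length(background_poly_coeffs)) {
    if (is.null(names(background_poly_coeffs)))
      coeffs[seq_along(background_poly_coeffs)] <- background_poly_coeffs
    else {
      bad <- setdiff(names(background_poly_coeffs), cn)
      if (length(bad))
        stop("invalid phantom_spec field 'background_poly_coeffs': unknown term ",
             paste(bad, collapse = ", "))
      coeffs[names(background_poly_coeffs)] <- background_poly_coeffs
    }
  }
  for (b in blob_params)
    if (!all(c("centre", "sd", "amplitude") %in% names(b)) ||
        length(b$centre) != 3L || b$sd <= 0)
      stop("invalid phantom_spec field 'blob_params'")
  if (!is.null(resection)) {
    if (!all(c("centre", "radii", "rim_amplitude", "rim_width") %in%
             names(resection)) ||
        length(resection$centre) != 3L || length(resection$radii) != 3L ||
        any(resection$radii <= 0) || resection$rim_width <= 0)
      stop("invalid phantom_spec field 'resection'")
    if (resection$rim_amplitude > 4 * resection$rim_width)
      warning("resection rim_amplitude > 4 * rim_width: adjacent phase steps ",
              "may exceed pi and break the smoothness precondition")
  }
  if (length(mask_radius) != 3L || any(mask_radius <= 0))
    stop("invalid phantom_spec field 'mask_radius'")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 background_poly_coeffs = coeffs,
                 blob_params = blob_params, resection = resection,
                 mask_radius = as.numeric(mask_radius),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Noise specification for synthetic phase data
#'
#' Two noise modes. `phase_gaussian` adds i.i.d. Gaussian noise of the given
#' variance directly to an unwrapped phase volume (the model used for the
#' simulation study: noise is added to the ground-truth unwrapped phase,
#' which is then re-wrapped). `complex_channel` adds i.i.d. Gaussian noise of
#' sd `sigma_channel` to the real and imaginary channels of the complex
#' signal `A * exp(i * phi)` and returns the angle of the result, which
#' reproduces the exact phase-noise distribution: uniform where `A = 0` and
#' approximately `N(0, (sigma/A)^2)` where `A >> sigma`.
#'
#' @param mode `"phase_gaussian"` or `"complex_channel"`.
#' @param variance phase-noise variance, radians^2 (`phase_gaussian`).
#' @param sigma_channel channel noise sd in magnitude units
#'   (`complex_channel`).
#' @param seed integer RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("phase_gaussian", "complex_channel"),
                       variance = 0, sigma_channel = 0, seed = 0L) {
  mode <- match.arg(mode)
  if (variance < 0) stop("variance must be >= 0")
  if (sigma_channel < 0) stop("sigma_channel must be >= 0")
  structure(list(mode = mode, variance = variance,
                 sigma_channel = sigma_channel, seed = as.integer(seed)),
            class = "noise_spec")
}

# normalised ellipsoid radius rho(x; centre, radii), 0-based voxel coords
ellipsoid_rho <- function(co, centre, radii) {
  sqrt(((co$x - centre[1]) / radii[1])^2 +
       ((co$y - centre[2]) / radii[2])^2 +
       ((co$z - centre[3]) / radii[3])^2)
}

#' Generate the ground-truth (unwrapped) phantom phase
#'
#' Background polynomial plus Gaussian bumps plus, if a resection is
#' specified, a radial Gaussian ridge on the cavity rim. Deterministic for a
#' fixed spec. With the default spec the phase spans more than 2*pi (so
#' wrapping is nontrivial) while adjacent differences stay below pi inside
#' the mask.
#'
#' @param spec a [phantom_spec()].
#' @return An unwrapped `phase_volume`.
#' @export
generate_true_phase <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  co <- coord_arrays(dims)
  # normalised coordinates in [-1, 1]
  u <- (co$x - (dims[1] - 1) / 2) / ((dims[1] - 1) / 2)
  v <- (co$y - (dims[2] - 1) / 2) / ((dims[2] - 1) / 2)
  w <- (co$z - (dims[3] - 1) / 2) / ((dims[3] - 1) / 2)
  p <- spec$background_poly_coeffs
  phi <- p["const"] + p["x"] * u + p["y"] * v + p["z"] * w +
    p["xx"] * u^2 + p["yy"] * v^2 + p["zz"] * w^2 +
    p["xy"] * u * v + p["xz"] * u * w + p["yz"] * v * w
  for (b in spec$blob_params) {
    d2 <- (co$x - b$centre[1])^2 + (co$y - b$centre[2])^2 +
      (co$z - b$centre[3])^2
    phi <- phi + b$amplitude * exp(-d2 / (2 * b$sd^2))
  }
  if (!is.null(spec$resection)) {
    r <- spec$resection
    rho <- ellipsoid_rho(co, r$centre, r$radii)
    rbar <- mean(r$radii)
    phi <- phi + r$rim_amplitude *
      exp(-((rho - 1) * rbar)^2 / (2 * r$rim_width^2))
  }
  dim(phi) <- dims
  phase_volume(phi, wrapped = FALSE, voxel_size = spec$voxel_size)
}

#' Generate the phantom magnitude image
#'
#' A high plateau (value 100) inside the head mask with a smooth roll-off at
#' the mask edge, near zero outside, and a deep low-signal resection cavity
#' (3% of the plateau throughout the cavity, i.e. < 10% at its centre) whose
#' signal recovers smoothly over a collar of about `2 * rim_width` voxels
#' outside the cavity boundary -- the partial-volume signal loss seen at a
#' real resection margin, and the reason the cavity rim is a low-quality,
#' low-confidence area. Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return A `magnitude_volume`.
#' @export
generate_magnitude <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  co <- coord_arrays(dims)
  centre <- (dims - 1) / 2
  rho <- ellipsoid_rho(co, centre, spec$mask_radius)
  edge <- 0.08                       # roll-off width in normalised radius
  m <- 100 * pmin(pmax((1 - rho) / edge, 0), 1)
  if (!is.null(spec$resection)) {
    r <- spec$resection
    rr <- ellipsoid_rho(co, r$centre, r$radii)
    # signed distance (approx. voxels) outside the cavity boundary
    d <- (rr - 1) * mean(r$radii)
    s <- pmin(pmax(d / (2 * r$rim_width), 0), 1)
    m <- m * (0.03 + 0.97 * (3 * s^2 - 2 * s^3))
  }
  dim(m) <- dims
  magnitude_volume(m, voxel_size = spec$voxel_size)
}

#' Head mask of the phantom
#'
#' Logical array: inside the head-mask ellipsoid.
#'
#' @param spec a [phantom_spec()].
#' @return A logical 3D array.
#' @export
phantom_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  co <- coord_arrays(dims)
  rho <- ellipsoid_rho(co, (dims - 1) / 2, spec$mask_radius)
  out <- rho <= 1
  dim(out) <- dims
  out
}

#' Add noise to a phase volume
#'
#' See [noise_spec()] for the two noise models. In `complex_channel` mode the
#' returned phase is the angle of the noisy complex signal, so it lies in
#' (-pi, pi] and is flagged wrapped; no unwrapped continuation is attempted.
#' Deterministic for a fixed seed.
#'
#' @param phase a `phase_volume` (unwrapped for `phase_gaussian` mode).
#' @param noise a [noise_spec()].
#' @param magnitude a `magnitude_volume`, required for `complex_channel`.
#' @return A `phase_volume`.
#' @export
add_phase_noise <- function(phase, noise, magnitude = NULL) {
  stopifnot(inherits(phase, "phase_volume"), inherits(noise, "noise_spec"))
  if (noise$mode == "phase_gaussian") {
    if (phase$wrapped)
      stop("phase_gaussian noise is added to an unwrapped phase volume")
    if (noise$variance == 0) return(phase)
    eps <- with_seed(noise$seed,
                     rnorm(length(phase$data), sd = sqrt(noise$variance)))
    out <- phase$data + array(eps, dim(phase$data))
    return(phase_volume(out, wrapped = FALSE, voxel_size = phase$voxel_size))
  }
  # complex_channel
  if (is.null(magnitude))
    stop("complex_channel noise requires a magnitude volume")
  stopifnot(inherits(magnitude, "magnitude_volume"))
  if (!all(dim(magnitude$data) == dim(phase$data)))
    stop("magnitude and phase grids differ")
  n <- length(phase$data)
  eps <- with_seed(noise$seed, rnorm(2 * n, sd = max(noise$sigma_channel, 0)))
  re <- magnitude$data * cos(phase$data) + array(eps[1:n], dim(phase$data))
  im <- magnitude$data * sin(phase$data) + array(eps[(n + 1):(2 * n)],
                                                 dim(phase$data))
  ang <- atan2(im, re)
  ang[ang <= -pi] <- pi              # atan2 returns [-pi, pi]; use (-pi, pi]
  phase_volume(ang, wrapped = TRUE, voxel_size = phase$voxel_size)
}

#' Simulate a dual-echo phase pair from a fieldmap
#'
#' The accrued phase at echo time TE is `base + 2 * pi * f * TE`, wrapped to
#' the principal interval; the unwrapped phase difference between the echoes
#' is `2 * pi * f * (TE2 - TE1)`.
#'
#' @param fieldmap_hz a `field_map` or 3D array of off-resonance, Hz.
#' @param te1,te2 echo times, seconds (`te2 > te1 > 0`).
#' @param base_phase optional `phase_volume` common to both echoes.
#' @return A list with wrapped `phase_volume`s `echo1` and `echo2`.
#' @export
simulate_echo_pair <- function(fieldmap_hz, te1, te2, base_phase = NULL) {
  f <- as_volume_array(fieldmap_hz)
  if (!(te1 > 0) || te2 <= te1) stop("need te2 > te1 > 0")
  base <- if (is.null(base_phase)) 0 else base_phase$data
  vs <- if (inherits(fieldmap_hz, "field_map")) fieldmap_hz$voxel_size
        else c(1, 1, 1)
  list(echo1 = phase_volume(wrap_phase(base + 2 * pi * f * te1),
                            wrapped = TRUE, voxel_size = vs),
       echo2 = phase_volume(wrap_phase(base + 2 * pi * f * te2),
                            wrapped = TRUE, voxel_size = vs))
}

#' Simulate a susceptibility-distorted EPI image
#'
#' Applies the forward distortion model along the phase-encode axis: signal
#' at true position y appears at `y + d(y)`. The distorted image is computed
#' by inverting the (assumed monotone) map per PE line; with
#' `modulate_jacobian` the intensities are divided by the local stretch
#' (multiplied by the Jacobian of the inverse map), which conserves total
#' intensity of compactly supported images. Non-monotone (folded) lines are
#' handled by clamping with a warning.
#'
#' @param image 3D array (or volume container), the undistorted image.
#' @param disp a `displacement_field` along the PE axis, voxels.
#' @param modulate_jacobian multiply by the Jacobian of the inverse map.
#' @return A 3D array, the distorted image.
#' @export
simulate_distorted_epi <- function(image, disp, modulate_jacobian = TRUE) {
  img <- as_volume_array(image)
  stopifnot(inherits(disp, "displacement_field"))
  if (!all(dim(disp$data) == dim(img)))
    stop("displacement field shape mismatch")
  axis <- disp$pe_axis
  n <- dim(img)[axis]
  folded <- FALSE
  idx <- 0L
  dperm <- c(axis, setdiff(1:3, axis))
  dmat <- matrix(aperm(disp$data, dperm), nrow = n)
  out <- apply_along(img, axis, function(line) {
    idx <<- idx + 1L
    d <- dmat[, idx]
    y <- seq_len(n)
    h <- y + d
    if (any(diff(h) <= 0)) {
      folded <<- TRUE
      h <- cummax(h) + seq_len(n) * 1e-9   # clamp to a monotone map
    }
    hinv <- approx(h, y, xout = y, rule = 1)$y
    val <- splinefun(y, line, method = "natural")(hinv)
    val[is.na(hinv)] <- 0
    if (modulate_jacobian) {
      # central-difference Jacobian of the inverse map
      g <- rep(1, n)
      g[2:(n - 1)] <- (hinv[3:n] - hinv[1:(n - 2)]) / 2
      g[1] <- hinv[2] - hinv[1]
      g[n] <- hinv[n] - hinv[n - 1]
      g[is.na(g)] <- 1
      val <- val * g
    }
    val[is.na(val)] <- 0
    val
  })
  if (folded)
    warning("displacement field folds along the PE axis; clamped to a ",
            "monotone map")
  out
}
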