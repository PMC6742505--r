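#' Phase volume
#'
#' A 3D scalar field of phase values in radians, flagged as wrapped (values
#' confined to the principal interval (-pi, pi]) or unwrapped (free phase).
#'
#' @param data 3D numeric array of phase values, radians.
#' @param wrapped logical; if `TRUE` all values must lie in (-pi, pi].
#' @param voxel_size numeric length-3, mm per axis.
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(data, wrapped, voxel_size = c(1, 1, 1)) {
  data <- as_volume_array(data)
  stopifnot(is.logical(wrapped), length(wrapped) == 1L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (wrapped) {
    bad <- data <= -pi - 1e-9 | data > pi + 1e-9
    if (any(bad))
      stop("wrapped phase values must lie in (-pi, pi]; ",
           sum(bad), " voxels outside")
  }
  structure(list(data = data, wrapped = wrapped,
                 voxel_size = as.numeric(voxel_size)),
            class = "phase_volume")
}

#' Magnitude volume
#'
#' @param data 3D numeric array of nonnegative magnitudes, arbitrary units.
#' @param voxel_size numeric length-3, mm per axis.
#' @return An object of class `magnitude_volume`.
#' @export
magnitude_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- as_volume_array(data)
  if (any(data < 0)) stop("magnitude values must be >= 0")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "magnitude_volume")
}

#' B0 fieldmap in Hz
#'
#' Off-resonance frequency per voxel, f = gamma * dB0 / (2 pi). Carrying the
#' field in Hz folds the gyromagnetic ratio into the representation, so the
#' displacement relation is simply delta_PE = f * T_acq (in voxels).
#'
#' @param data 3D numeric array, Hz.
#' @param voxel_size numeric length-3, mm per axis.
#' @return An object of class `field_map`.
#' @export
field_map <- function(data, voxel_size = c(1, 1, 1)) {
  data <- as_volume_array(data)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "field_map")
}

#' Phase-encode displacement field
#'
#' Scalar per-voxel displacement along the phase-encode axis, in voxels.
#'
#' @param data 3D numeric array, voxels.
#' @param pe_axis phase-encode axis index (1, 2 or 3).
#' @param pe_sign +1 or -1, the sign convention of the phase-encode blips.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(data, pe_axis = 2L, pe_sign = 1L) {
  data <- as_volume_array(data)
  pe_axis <- as.integer(pe_axis)
  if (!pe_axis %in% 1:3) stop("pe_axis must be 1, 2 or 3")
  if (!pe_sign %in% c(-1L, 1L)) stop("pe_sign must be +1 or -1")
  if (any(!is.finite(data))) stop("displacement field must be finite")
  if (any(abs(data) >= dim(data)[pe_axis]))
    stop("|displacement| must be smaller than the phase-encode extent")
  structure(list(data = data, pe_axis = pe_axis, pe_sign = as.integer(pe_sign)),
            class = "displacement_field")
}

#' Per-voxel unwrapping confidence
#'
#' @param omega 3D numeric array of confidences in (0, 1].
#' @param provenance character note on the move problem that produced it.
#' @return An object of class `confidence_map`.
#' @export
confidence_map <- function(omega, provenance = "") {
  omega <- as_volume_array(omega)
  if (any(omega <= 0 | omega > 1 + 1e-12))
    stop("confidence values must lie in (0, 1]")
  structure(list(omega = omega, provenance = provenance),
            class = "confidence_map")
}

# accept a bare array or any of the volume containers
as_volume_array <- function(x) {
  if (inherits(x, c("phase_volume", "magnitude_volume", "field_map",
                    "displacement_field")))
    return(x$data)
  if (inherits(x, "confidence_map")) return(x$omega)
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    if (is.numeric(x) && !is.null(dim(x)) && length(dim(x)) == 2L)
      dim(x) <- c(dim(x), 1L)
    else if (is.numeric(x) && is.null(dim(x)))
      dim(x) <- c(length(x), 1L, 1L)
    else stop("expected a 3D numeric array")
  }
  storage.mode(x) <- "double"
  x
}

#' Wrap phase into the principal interval (-pi, pi]
#'
#' Maps every value to its principal representative; the output is congruent
#' to the input modulo 2*pi to machine precision. Ties at the boundary follow
#' the (-pi, pi] convention: both pi and -pi map to +pi.
#'
#' @param phase a `phase_volume`, or any numeric array/vector of radians.
#' @return An object of the same shape; `phase_volume` in, wrapped
#'   `phase_volume` out, otherwise a numeric object.
#' @examples
#' wrap_phase(3 * pi / 2)   # -pi/2
#' wrap_phase(c(-pi, pi))   # both map to pi
#' @export
wrap_phase <- function(phase) {
  if (inherits(phase, "phase_volume")) {
    return(phase_volume(wrap_phase(phase$data), wrapped = TRUE,
                        voxel_size = phase$voxel_size))
  }
  w <- phase - 2 * pi * ceiling((phase - pi) / (2 * pi))
  # guard against rounding at the boundary
  w[w > pi] <- w[w > pi] - 2 * pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' @export
print.phase_volume <- function(x, ...) {
  cat(sprintf("<phase_volume %s, %s, range [%.3f, %.3f] rad>\n",
              paste(dim(x$data), collapse = "x"),
              if (x$wrapped) "wrapped" else "unwrapped",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.magnitude_volume <- function(x, ...) {
  cat(sprintf("<magnitude_volume %s, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map %s, range [%.2f, %.2f] Hz>\n",
              paste(dim(x$data), collapse = "x"), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field %s, PE axis %d (sign %+d), |d| max %.2f vox>\n",
              paste(dim(x$data), collapse = "x"), x$pe_axis, x$pe_sign,
              max(abs(x$data))))
  invisible(x)
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("<confidence_map %s, median %.4f>\n",
              paste(dim(x$omega), collapse = "x"), stats::median(x$omega)))
  invisible(x)
}
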