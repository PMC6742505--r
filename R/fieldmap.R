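#' Acquisition parameters for fieldmap-based correction
#'
#' @param te1,te2 echo times in seconds, `te2 > te1 > 0`.
#' @param tacq effective EPI readout time in seconds (total time between the
#'   acquisition of the first and last phase-encode line, after any parallel
#'   imaging acceleration).
#' @param pe_axis phase-encode axis (1, 2 or 3).
#' @param pe_sign +1 or -1.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(te1 = 0.008, te2 = 0.010, tacq = 0.05,
                               pe_axis = 2L, pe_sign = 1L) {
  if (!(te1 > 0) || te2 <= te1) stop("need te2 > te1 > 0")
  if (!(tacq > 0)) stop("tacq must be > 0")
  pe_axis <- as.integer(pe_axis)
  if (!pe_axis %in% 1:3) stop("pe_axis must be 1, 2 or 3")
  if (!pe_sign %in% c(-1, 1)) stop("pe_sign must be +1 or -1")
  structure(list(te1 = te1, te2 = te2, tacq = tacq, pe_axis = pe_axis,
                 pe_sign = as.integer(pe_sign)),
            class = "acquisition_params")
}

#' Wrapped phase difference of a dual-echo pair
#'
#' `wrap(phi2 - phi1)`: differencing the echoes eliminates phase
#' contributions common to both, leaving the off-resonance evolution over
#' the echo spacing.
#'
#' @param echo1_wrapped,echo2_wrapped wrapped `phase_volume`s on one grid.
#' @return A wrapped `phase_volume`.
#' @export
phase_difference <- function(echo1_wrapped, echo2_wrapped) {
  stopifnot(inherits(echo1_wrapped, "phase_volume"),
            inherits(echo2_wrapped, "phase_volume"))
  if (!all(dim(echo1_wrapped$data) == dim(echo2_wrapped$data)))
    stop("echo grids differ")
  phase_volume(wrap_phase(echo2_wrapped$data - echo1_wrapped$data),
               wrapped = TRUE, voxel_size = echo1_wrapped$voxel_size)
}

#' Fieldmap (Hz) from the unwrapped phase difference
#'
#' `f = delta_theta / (2 * pi * delta_TE)`: the off-resonance frequency in
#' Hz, i.e. the B0 inhomogeneity with the gyromagnetic ratio folded in.
#'
#' @param delta_phi unwrapped `phase_volume` (the unwrapped echo
#'   difference).
#' @param params an [acquisition_params()].
#' @return A `field_map`.
#' @export
fieldmap_from_unwrapped_difference <- function(delta_phi, params) {
  stopifnot(inherits(delta_phi, "phase_volume"),
            inherits(params, "acquisition_params"))
  if (delta_phi$wrapped)
    stop("delta_phi must be unwrapped (run unwrap() on the wrapped ",
         "difference first)")
  dte <- params$te2 - params$te1
  if (dte <= 0) stop("delta TE must be > 0")
  field_map(delta_phi$data / (2 * pi * dte),
            voxel_size = delta_phi$voxel_size)
}

#' Phase-encode displacement field from a fieldmap
#'
#' `displacement_voxels = pe_sign * f_Hz * tacq`, linear in the fieldmap.
#'
#' @param fmap a `field_map`.
#' @param params an [acquisition_params()].
#' @return A `displacement_field`.
#' @export
displacement_from_fieldmap <- function(fmap, params) {
  stopifnot(inherits(fmap, "field_map"),
            inherits(params, "acquisition_params"))
  displacement_field(params$pe_sign * fmap$data * params$tacq,
                     pe_axis = params$pe_axis, pe_sign = params$pe_sign)
}

#' Correct a distorted EPI volume with a displacement field
#'
#' Undoes the forward distortion `y -> y + d(y)` along the phase-encode
#' axis: the corrected intensity at true position y is the distorted image
#' sampled (1D cubic interpolation) at `y + d(y)`, multiplied by the 1D
#' Jacobian `1 + dd/dy` of the applied map when `modulate_jacobian` is on,
#' which undoes signal pile-up and conserves total intensity. Samples
#' falling outside the field of view take the value 0. Voxels where the
#' Jacobian is not positive (a folded field) are clamped to a small
#' positive floor with a warning.
#'
#' @param epi 3D array (or container), the distorted EPI image.
#' @param disp a `displacement_field`.
#' @param modulate_jacobian logical.
#' @return A 3D array, the corrected image.
#' @export
correct_epi <- function(epi, disp, modulate_jacobian = TRUE) {
  img <- as_volume_array(epi)
  stopifnot(inherits(disp, "displacement_field"))
  if (!all(dim(disp$data) == dim(img)))
    stop("displacement field shape mismatch")
  axis <- disp$pe_axis
  n <- dim(img)[axis]
  dperm <- c(axis, setdiff(1:3, axis))
  dmat <- matrix(aperm(disp$data, dperm), nrow = n)
  idx <- 0L
  clamped <- FALSE
  out <- apply_along(img, axis, function(line) {
    idx <<- idx + 1L
    d <- dmat[, idx]
    y <- seq_len(n)
    src <- y + d
    val <- splinefun(y, line, method = "natural")(src)
    val[src < 1 | src > n] <- 0
    if (modulate_jacobian) {
      jac <- rep(1, n)
      jac[2:(n - 1)] <- 1 + (d[3:n] - d[1:(n - 2)]) / 2
      jac[1] <- 1 + (d[2] - d[1])
      jac[n] <- 1 + (d[n] - d[n - 1])
      if (any(jac <= 0)) {
        clamped <<- TRUE
        jac <- pmax(jac, 0.05)
      }
      val <- val * jac
    }
    val
  })
  if (clamped)
    warning("non-positive Jacobian (folded displacement field); ",
            "clamped at 0.05")
  out
}
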