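#' Misclassification ratio of an unwrapping solution
#'
#' Fraction of masked voxels whose wrap count is wrong after removing the
#' single global integer offset that maximises agreement (the mode of
#' `k_est - k_true` inside the mask). The MRF energy is invariant under a
#' global shift of the counts, so without this gauge fixing the ratio would
#' be ill-defined up to a constant.
#'
#' @param k_est,k_true integer 3D arrays of wrap counts (or `unwrap_result`
#'   counts).
#' @param mask logical array of voxels to evaluate; `NULL` evaluates the
#'   whole grid.
#' @return An object of class `mcr_report`: `mcr` in \[0, 1\], `n_masked`,
#'   and the removed `global_offset`.
#' @export
mcr <- function(k_est, k_true, mask = NULL) {
  if (inherits(k_est, "unwrap_result")) k_est <- k_est$counts
  if (inherits(k_true, "unwrap_result")) k_true <- k_true$counts
  k_est <- as_volume_array(k_est); k_true <- as_volume_array(k_true)
  if (!all(dim(k_est) == dim(k_true))) stop("count map grids differ")
  if (is.null(mask)) mask <- array(TRUE, dim(k_est))
  if (!any(mask)) stop("empty mask")
  d <- round(k_est[mask] - k_true[mask])
  tab <- table(d)
  offset <- as.integer(names(tab)[which.max(tab)])
  wrong <- sum(d != offset)
  structure(list(mcr = wrong / length(d), n_masked = length(d),
                 global_offset = offset),
            class = "mcr_report")
}

#' @export
print.mcr_report <- function(x, ...) {
  cat(sprintf("<mcr_report mcr %.4f over %d voxels (global offset %+d)>\n",
              x$mcr, x$n_masked, x$global_offset))
  invisible(x)
}

#' Normalised sum-of-squares residual of a signal fit
#'
#' `chi^2 = sum((S_m - S_f)^2) / sum(S_m^2)`: a dimensionless fit residual,
#' invariant under common positive rescaling of measured and fitted
#' signals. Used to quantify diffusion tensor fit quality.
#'
#' @param s_measured,s_fitted numeric vectors of N signals.
#' @return Nonnegative scalar.
#' @export
chi_squared_residual <- function(s_measured, s_fitted) {
  if (length(s_measured) < 1L || length(s_measured) != length(s_fitted))
    stop("signal vectors must be nonempty and of equal length")
  denom <- sum(s_measured^2)
  if (denom == 0) stop("all-zero measured signal")
  sum((s_measured - s_fitted)^2) / denom
}
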