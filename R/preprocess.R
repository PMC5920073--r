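#' Denoise an intensity stack
#'
#' Median or Gaussian smoothing with a per-axis window, in voxel units.
#' The median filter uses a box window of `2 * radius + 1` voxels per axis
#' (always odd) and never creates values outside the input range; the
#' Gaussian filter interprets `radius_vox` as the per-axis sigma in voxels.
#' A radius of 0 on every axis is the identity.
#'
#' @param stack an [intensity_stack()].
#' @param method `"median"` or `"gaussian"`.
#' @param radius_vox per-axis window, `(z, y, x)` order; non-negative.
#'   A scalar is recycled to all three axes.
#' @return A denoised [intensity_stack()] with the same shape, calibration
#'   and channel.
#' @export
denoise <- function(stack, method = c("median", "gaussian"),
                    radius_vox = c(1, 1, 1)) {
  method <- match.arg(method)
  if (!inherits(stack, "intensity_stack")) stop("not an intensity_stack")
  if (length(radius_vox) == 1) radius_vox <- rep(radius_vox, 3)
  if (length(radius_vox) != 3 || any(radius_vox < 0))
    stop("radius_vox must be three non-negative values (z, y, x)")
  d <- dim(stack)
  v <- as.numeric(stack)
  out <- if (all(radius_vox == 0)) {
    v
  } else if (method == "median") {
    median3d_cpp(v, d, as.integer(round(radius_vox)))
  } else {
    gauss3d_cpp(v, d, as.numeric(radius_vox))
  }
  out <- pmax(out, 0)
  intensity_stack(array(out, d), calibration_of(stack),
                  channel = attr(stack, "channel"))
}

#' Flatten non-uniform illumination
#'
#' Estimates a smooth per-slice (2D) background by Gaussian smoothing at a
#' scale much larger than any droplet, subtracts it, and clips at zero.
#' Shading in confocal stacks varies with depth, so each z-slice is
#' corrected independently.
#'
#' @param stack an [intensity_stack()].
#' @param sigma_um in-plane smoothing scale in micrometers; should be well
#'   above the droplet diameter scale (a warning is issued below 10 um).
#' @return A corrected [intensity_stack()], same shape and calibration.
#' @export
correct_illumination <- function(stack, sigma_um = 20) {
  if (!inherits(stack, "intensity_stack")) stop("not an intensity_stack")
  if (!is.finite(sigma_um) || sigma_um <= 0)
    stop("sigma_um must be strictly positive")
  if (sigma_um < 10)
    warning("sigma_um < 10 um: background estimate may follow the droplets themselves")
  cal <- calibration_of(stack)
  sig_vox <- c(0, sigma_um / cal[["dy_um"]], sigma_um / cal[["dx_um"]])
  d <- dim(stack)
  bg <- gauss3d_cpp(as.numeric(stack), d, sig_vox)
  out <- pmax(as.numeric(stack) - bg, 0)
  intensity_stack(array(out, d), cal, channel = attr(stack, "channel"))
}
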