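#' Voxel calibration
#'
#' Physical pitch of one voxel along each axis, in micrometers. Confocal
#' stacks are typically anisotropic: the slice spacing (`dz_um`) is larger
#' than the in-plane pixel pitch. The default values correspond to a
#' 100x oil-immersion acquisition at 800 x 800 px over a 127 x 127 um field
#' (0.159 um/px in x and y) with 0.38 um between optical sections.
#'
#' @param dx_um,dy_um,dz_um pixel pitch along x and y, and slice spacing
#'   along z, all in micrometers. Must be strictly positive and finite.
#' @return An object of class `ld3d_calibration`: a named numeric vector
#'   with elements `dx_um`, `dy_um`, `dz_um`.
#' @examples
#' cal <- calibration()
#' voxel_volume(cal)
#' @export
calibration <- function(dx_um = 0.159, dy_um = 0.159, dz_um = 0.38) {
  v <- c(dx_um = as.numeric(dx_um), dy_um = as.numeric(dy_um),
         dz_um = as.numeric(dz_um))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("calibration components must be strictly positive and finite")
  structure(v, class = "ld3d_calibration")
}

#' @export
print.ld3d_calibration <- function(x, ...) {
  cat(sprintf("voxel calibration: %.4g x %.4g x %.4g um (x, y, z); %.4g um^3/voxel\n",
              x[["dx_um"]], x[["dy_um"]], x[["dz_um"]], voxel_volume(x)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' The product of the three calibration pitches, in cubic micrometers.
#' Object volumes are voxel counts multiplied by this quantity.
#'
#' @param cal an [calibration()] object.
#' @return Voxel volume in um^3.
#' @export
voxel_volume <- function(cal) {
  cal <- as_calibration(cal)
  unname(cal[["dx_um"]] * cal[["dy_um"]] * cal[["dz_um"]])
}

as_calibration <- function(x) {
  if (inherits(x, "ld3d_calibration")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    if (!is.null(names(x)) && all(c("dx_um", "dy_um", "dz_um") %in% names(x)))
      return(calibration(x[["dx_um"]], x[["dy_um"]], x[["dz_um"]]))
    return(calibration(x[[1]], x[[2]], x[[3]]))
  }
  stop("not a calibration: expected ld3d_calibration or numeric length 3")
}

# spacing per axis in array (z, y, x) order, for distance computations
cal_spacing_zyx <- function(cal) {
  cal <- as_calibration(cal)
  unname(c(cal[["dz_um"]], cal[["dy_um"]], cal[["dx_um"]]))
}

calibration_equal <- function(a, b, tol = 1e-9) {
  a <- as_calibration(a); b <- as_calibration(b)
  all(abs(unclass(a) - unclass(b)) <= tol * pmax(abs(unclass(a)), 1))
}
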