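#' Calibrated intensity stack
#'
#' A 3D grayscale image indexed `[z, y, x]` (slice, row, column) with a
#' voxel [calibration()] attached. Values are non-negative; integer pixel
#' types are widened to double on construction.
#'
#' @param voxels 3D numeric array with `dim = c(nz, ny, nx)`.
#' @param cal voxel calibration.
#' @param channel `"fluorescence"` (droplet signal) or `"brightfield"`
#'   (cell-boundary signal).
#' @return An `intensity_stack`: the array with `calibration` and `channel`
#'   attributes.
#' @export
intensity_stack <- function(voxels, cal = calibration(),
                            channel = c("fluorescence", "brightfield")) {
  channel <- match.arg(channel)
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array (z, y, x)")
  if (any(dim(voxels) < 1)) stop("all stack dimensions must be >= 1")
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(voxels < 0))
    stop("voxel values must be non-negative and non-missing")
  structure(voxels, calibration = as_calibration(cal), channel = channel,
            class = c("intensity_stack", "array"))
}

#' Label volume
#'
#' A 3D map of non-negative integer labels indexed `[z, y, x]`; label 0 is
#' background. Positive labels need not be contiguous integers.
#'
#' @param labels 3D integer array.
#' @param cal voxel calibration.
#' @param kind `"droplet"` or `"cell"`.
#' @return A `label_volume`.
#' @export
label_volume <- function(labels, cal = calibration(),
                         kind = c("droplet", "cell")) {
  kind <- match.arg(kind)
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("labels must be a 3D array (z, y, x)")
  if (anyNA(labels)) stop("labels must not contain missing values")
  if (any(labels < 0)) stop("labels must be non-negative")
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  structure(labels, calibration = as_calibration(cal), kind = kind,
            class = c("label_volume", "array"))
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("intensity stack (%s): %d x %d x %d voxels (z, y, x), range [%g, %g]\n",
              attr(x, "channel"), d[1], d[2], d[3], min(x), max(x)))
  print(attr(x, "calibration"))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("label volume (%s): %d x %d x %d voxels (z, y, x), %d labels\n",
              attr(x, "kind"), d[1], d[2], d[3], length(positive_labels(x))))
  print(attr(x, "calibration"))
  invisible(x)
}

#' Calibration of a volume
#' @param x an `intensity_stack`, `label_volume` or mask with a calibration
#'   attribute.
#' @return The attached [calibration()].
#' @export
calibration_of <- function(x) {
  cal <- attr(x, "calibration")
  if (is.null(cal)) stop("object carries no calibration")
  as_calibration(cal)
}

positive_labels <- function(labels) {
  u <- unique(as.integer(labels))
  sort(u[u > 0])
}

# shared geometry contract: same dims and same calibration
check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have different shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  if (!calibration_equal(calibration_of(a), calibration_of(b)))
    stop(sprintf("%s have different calibrations; resample explicitly", what))
  invisible(TRUE)
}

# rebuild a label_volume around a plain integer array, reusing metadata
relabel_like <- function(labels_arr, template) {
  label_volume(labels_arr, calibration_of(template),
               kind = attr(template, "kind") %||% "droplet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
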