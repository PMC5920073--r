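#' Read a multi-page grayscale TIFF as an intensity stack
#'
#' Pages map to z in file order; integer pixel values are widened losslessly
#' to double. If a metadata sidecar (`<path>.json`, written by
#' [write_stack()]) is present and carries a complete calibration, it
#' overrides the `cal` argument.
#'
#' @param path TIFF file path.
#' @param cal fallback [calibration()] used when the file carries none.
#' @param channel channel tag used when the file carries none.
#' @return An [intensity_stack()].
#' @export
read_stack <- function(path, cal = calibration(),
                       channel = c("fluorescence", "brightfield")) {
  channel <- match.arg(channel)
  pages <- read_tiff_pages(path)
  meta <- read_sidecar(path)
  if (!is.null(meta$calibration)) cal <- meta$calibration
  if (!is.null(meta$channel)) channel <- meta$channel
  intensity_stack(pages_to_array(pages), cal, channel)
}

#' Write an intensity stack as a 16-bit multi-page TIFF
#'
#' Values must be integers in `[0, 65535]`; the round trip through
#' [read_stack()] is then value-identical. Calibration and channel are
#' stored in a JSON sidecar `<path>.json`.
#'
#' @param stack an [intensity_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "intensity_stack")) stop("not an intensity_stack")
  v <- unclass(stack)
  if (any(v != round(v)) || max(v) > 65535)
    stop("intensity stacks are stored as 16-bit integers; values must be whole numbers in [0, 65535]")
  pages <- array_to_pages(v / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  write_sidecar(path, calibration_of(stack),
                type = "intensity", tag = attr(stack, "channel"))
  invisible(path)
}

#' Write a label volume as a multi-page TIFF
#'
#' Chooses 8- or 16-bit unsigned storage when the maximum label fits, and
#' 32-bit float storage (fixed 2^24 scale) otherwise; all three round-trip
#' losslessly through [read_label_volume()]. Labels above 2^24 - 1 overflow
#' every supported depth and are an error.
#'
#' @param labels a [label_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  if (!inherits(labels, "label_volume")) stop("not a label_volume")
  v <- unclass(labels)
  mx <- max(v)
  if (mx > 2^24 - 1)
    stop("label overflow: labels above 2^24 - 1 cannot be stored exactly")
  if (mx <= 255) {
    bits <- 8L; scale <- 255
  } else if (mx <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    bits <- 32L; scale <- 2^24
  }
  pages <- array_to_pages(v / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  write_sidecar(path, calibration_of(labels),
                type = "label", tag = attr(labels, "kind"), scale = scale)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param path TIFF file path.
#' @param cal fallback calibration when the sidecar is absent.
#' @param kind fallback kind tag.
#' @return A [label_volume()], voxel-for-voxel equal to what was written.
#' @export
read_label_volume <- function(path, cal = calibration(),
                              kind = c("droplet", "cell")) {
  kind <- match.arg(kind)
  pages <- read_tiff_pages(path)
  meta <- read_sidecar(path)
  if (!is.null(meta$calibration)) cal <- meta$calibration
  if (!is.null(meta$kind)) kind <- meta$kind
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  arr <- pages_to_array(pages)
  if (bits >= 32) {
    scale <- meta$scale %||% 2^24
    arr <- round(arr * scale)
  }
  label_volume(arr, cal, kind)
}

# ---- internals ------------------------------------------------------------

# Integer depths are read with as.is = TRUE (exact stored integers); 32-bit
# float pages must be read without as.is, which returns the raw float.
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop(sprintf("zero pages in TIFF: %s", path))
  info <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, payload = FALSE),
    error = function(e) stop(sprintf("zero pages or unreadable TIFF (%s): %s",
                                     conditionMessage(e), path)))
  # payload = FALSE returns a data frame of per-page TIFF directories
  bits <- if (is.data.frame(info) && !is.null(info$bits.per.sample))
    as.integer(info$bits.per.sample)
  else 16L
  if (NROW(info) == 0) stop(sprintf("zero pages in TIFF: %s", path))
  use_as_is <- all(bits < 32)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = use_as_is)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2))
    stop("non-grayscale TIFF: every page must be a single-channel 2D image")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("ragged TIFF: pages have differing shapes")
  pages
}

pages_to_array <- function(pages) {
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  arr
}

array_to_pages <- function(arr) {
  lapply(seq_len(dim(arr)[1]), function(z) arr[z, , , drop = TRUE])
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, cal, type, tag, scale = NULL) {
  meta <- list(format = "ld3d-volume", type = type, tag = tag,
               dx_um = cal[["dx_um"]], dy_um = cal[["dy_um"]],
               dz_um = cal[["dz_um"]])
  if (!is.null(scale)) meta$scale <- scale
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  out <- list(calibration = NULL, channel = NULL, kind = NULL, scale = NULL)
  if (!file.exists(sp)) return(out)
  meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta) || !identical(meta$format, "ld3d-volume")) return(out)
  if (all(c("dx_um", "dy_um", "dz_um") %in% names(meta)))
    out$calibration <- calibration(meta$dx_um, meta$dy_um, meta$dz_um)
  if (identical(meta$type, "intensity")) out$channel <- meta$tag
  if (identical(meta$type, "label")) out$kind <- meta$tag
  if (!is.null(meta$scale)) out$scale <- meta$scale
  out
}
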