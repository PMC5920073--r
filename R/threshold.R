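#' Otsu threshold level of a volume
#'
#' Computes the global Otsu level on a 256-bin histogram spanning the full
#' value range of the volume: the cut that maximizes the between-class
#' variance. Ties are broken toward the lowest cut, so the result is
#' deterministic. The returned level is the bin edge separating the two
#' classes; foreground is `value > level`.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold level (numeric scalar).
#' @export
otsu_level <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi)) stop("non-finite intensities")
  if (lo == hi)
    stop("cannot Otsu-threshold a constant volume: no separable classes")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  w <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  cw <- cumsum(w)                # class-0 weight after cut k
  cm <- cumsum(w * mids)         # class-0 unnormalized mean
  mu <- cm[n_bins]
  k <- seq_len(n_bins - 1)
  valid <- cw[k] > 0 & cw[k] < 1
  # between-class variance: w0*w1*(mu0 - mu1)^2
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mu * cw[k][valid] - cm[k][valid])^2 /
    (cw[k][valid] * (1 - cw[k][valid]))
  best <- which.max(bcv)         # ties -> smallest cut index
  breaks[best + 1]
}

#' Threshold a stack into a binary droplet mask
#'
#' @param stack an [intensity_stack()].
#' @param method `"otsu"` (global 256-bin Otsu) or `"fixed"`.
#' @param value threshold level, required for `method = "fixed"`.
#' @return A logical 3D array (`TRUE` = foreground, `value > level`) with
#'   the stack's calibration attached.
#' @export
threshold_stack <- function(stack, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (!inherits(stack, "intensity_stack")) stop("not an intensity_stack")
  level <- if (method == "otsu") {
    otsu_level(stack)
  } else {
    if (is.null(value)) stop("fixed thresholding requires a value")
    as.numeric(value)
  }
  mask <- array(as.vector(unclass(stack)) > level, dim(stack))
  attr(mask, "calibration") <- calibration_of(stack)
  attr(mask, "level") <- level
  mask
}
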