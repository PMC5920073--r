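#' 3D connected-component labeling
#'
#' Maximal connected components of a binary mask under 6-, 18- or
#' 26-adjacency receive distinct positive labels, numbered from 1 in order
#' of first encounter along the `(z, y, x)` raster (z varies fastest).
#'
#' @param mask logical 3D array (from [threshold_stack()] or constructed);
#'   a `calibration` attribute is used when `cal` is missing.
#' @param connectivity 6, 18 or 26 (default 26: bright blobs should not
#'   fragment on diagonal contact).
#' @param cal calibration for the output volume.
#' @param kind label kind for the output volume.
#' @return A [label_volume()].
#' @export
label_components <- function(mask, connectivity = 26, cal = NULL,
                             kind = c("droplet", "cell")) {
  kind <- match.arg(kind)
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("mask must be a 3D array")
  if (is.null(cal)) cal <- attr(mask, "calibration") %||% calibration()
  lab <- ccl3d_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  label_volume(array(lab, dim(mask)), cal, kind)
}

#' Remove components below a physical volume threshold
#'
#' Components whose physical volume (voxel count times voxel volume) is
#' strictly below `min_volume_um3` are relabeled to background. Surviving
#' labels are renumbered densely from 1, preserving first-encounter raster
#' order. Foreground voxels are only ever removed, never added.
#'
#' @param labels a [label_volume()].
#' @param min_volume_um3 threshold in um^3 (default 0.05, roughly five
#'   voxels at the default confocal calibration).
#' @return A filtered [label_volume()].
#' @export
filter_small <- function(labels, min_volume_um3 = 0.05) {
  if (!inherits(labels, "label_volume")) stop("not a label_volume")
  if (min_volume_um3 < 0) stop("min_volume_um3 must be >= 0")
  v <- as.integer(labels)
  if (max(v) == 0) return(labels)
  counts <- tabulate(v[v > 0], nbins = max(v))
  keep <- which(counts * voxel_volume(calibration_of(labels)) >= min_volume_um3)
  out <- renumber_raster_order(v, keep, dim(labels))
  relabel_like(out, labels)
}

# keep only `keep` labels, renumber 1..K by first-encounter raster order
renumber_raster_order <- function(v, keep, dims) {
  map <- integer(max(max(v), 1))
  if (length(keep)) {
    fg <- v[v %in% keep]
    first_order <- unique(fg)              # order of first occurrence
    map[first_order] <- seq_along(first_order)
  }
  out <- integer(length(v))
  pos <- v > 0
  out[pos] <- map[v[pos]]
  array(out, dims)
}

#' Split touching droplets by marker-controlled watershed
#'
#' Within each connected component, markers are local maxima of the
#' anisotropy-aware Euclidean distance transform (distances in physical
#' units) separated by at least `min_sep_um`; the component is then split
#' by a watershed flooded from the markers on the distance map. Components
#' with a single marker are left unchanged. The result is renumbered
#' densely in raster order.
#'
#' @param labels a [label_volume()] from [label_components()].
#' @param min_sep_um minimum marker separation in micrometers (default 2).
#' @param connectivity adjacency used while flooding (default 26).
#' @return A [label_volume()] with touching droplets split.
#' @export
split_touching <- function(labels, min_sep_um = 2, connectivity = 26) {
  if (!inherits(labels, "label_volume")) stop("not a label_volume")
  cal <- calibration_of(labels)
  sp <- cal_spacing_zyx(cal)
  dims <- dim(labels)
  v <- array(as.integer(labels), dims)
  ids <- positive_labels(v)
  if (length(ids) == 0) return(labels)
  out <- array(0L, dims)
  nxt <- 0L
  idx_all <- which(v > 0)
  zyx <- arrayInd(idx_all, dims)
  rows_by_id <- split(seq_along(idx_all), v[idx_all])
  for (id in ids) {
    co <- zyx[rows_by_id[[as.character(id)]], , drop = FALSE]
    lo <- pmax(apply(co, 2, min) - 1L, 1L)
    hi <- pmin(apply(co, 2, max) + 1L, dims)
    sub <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    m <- sub == id
    dsub <- dim(m)
    dist <- sqrt(edt_sq_cpp(!m, dsub, sp))   # depth inside the component
    marks <- find_local_maxima(array(dist, dsub), mask = m, sp = sp,
                               min_sep_um = min_sep_um)
    if (nrow(marks) <= 1) {
      pieces <- array(as.integer(m), dsub)
      npieces <- 1L
    } else {
      seeds <- array(0L, dsub)
      seeds[marks] <- seq_len(nrow(marks))
      pieces <- watershed_cpp(dist, as.integer(seeds), as.logical(m), dsub,
                              as.integer(connectivity))
      pieces <- array(pieces, dsub)
      npieces <- nrow(marks)
    }
    tgt <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    tgt[m] <- pieces[m] + nxt
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- tgt
    nxt <- nxt + npieces
  }
  out <- renumber_raster_order(as.integer(out), seq_len(max(nxt, 1L)), dims)
  relabel_like(out, labels)
}

# Regional maxima of `img` within `mask`: connected plateau components of
# the window-maximum condition, collapsed to one representative voxel each
# (the plateau voxel nearest its centroid), then greedily thinned so kept
# maxima are pairwise >= min_sep_um apart (physical units). Returns a
# (z, y, x) coordinate matrix, strongest first.
find_local_maxima <- function(img, mask, sp, min_sep_um) {
  dims <- dim(img)
  r <- pmax(1L, as.integer(round(min_sep_um / 2 / sp)))
  mx <- array(maxfilt3d_cpp(as.numeric(img), dims, r), dims)
  cand <- mask & img == mx & img > 0
  if (!any(cand)) return(matrix(integer(0), 0, 3))
  comp <- array(ccl3d_cpp(as.logical(cand), dims, 26L), dims)
  idx <- which(comp > 0)
  co_all <- arrayInd(idx, dims)
  reps <- t(vapply(split(seq_along(idx), comp[idx]), function(rows) {
    co <- co_all[rows, , drop = FALSE]
    ctr <- colMeans(co)
    d2 <- colSums((t(co) - ctr)^2)
    as.integer(co[which.min(d2), ])
  }, integer(3)))
  vals <- img[reps]
  ord <- order(-vals, reps[, 1], reps[, 2], reps[, 3])   # strongest, stable
  reps <- reps[ord, , drop = FALSE]
  pos <- sweep(reps, 2, sp, `*`)
  keep <- integer(0)
  for (i in seq_len(nrow(reps))) {
    if (length(keep)) {
      dd <- sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2))
      if (any(dd < min_sep_um)) next
    }
    keep <- c(keep, i)
  }
  reps[keep, , drop = FALSE]
}
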