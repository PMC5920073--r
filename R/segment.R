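#' Segment lipid droplets from a fluorescence stack
#'
#' Runs the full droplet pipeline: optional denoising and illumination
#' flattening, global thresholding, 3D connected components, physical size
#' filtering and (optionally) watershed splitting of touching droplets,
#' in that order. All steps are deterministic; the resolved configuration
#' is attached to the result.
#'
#' @param stack a fluorescence [intensity_stack()].
#' @param config pipeline configuration, see [default_config()]; only the
#'   `preprocess` and `segment` blocks are used.
#' @return A droplet [label_volume()] with a `config` attribute.
#' @export
segment_droplets <- function(stack, config = default_config()) {
  if (!inherits(stack, "intensity_stack")) stop("not an intensity_stack")
  config <- merge_config(config)
  pp <- config$preprocess
  sg <- config$segment
  x <- stack
  if (any(pp$denoise_radius > 0))
    x <- denoise(x, pp$denoise_method, pp$denoise_radius)
  if (!is.null(pp$illumination_sigma_um))
    x <- correct_illumination(x, pp$illumination_sigma_um)
  mask <- threshold_stack(x, sg$threshold_method, sg$threshold_value)
  labels <- label_components(mask, sg$connectivity, cal = calibration_of(stack))
  labels <- filter_small(labels, sg$min_volume_um3)
  if (isTRUE(sg$split_enabled))
    labels <- split_touching(labels, sg$split_min_sep_um, sg$connectivity)
  attr(labels, "config") <- config
  attr(labels, "threshold_level") <- attr(mask, "level")
  labels
}

#' Segment cells from a bright-field boundary stack
#'
#' Seeded 3D watershed on the boundary channel, in which cells are bright
#' and the intercellular matrix/walls are dark. The flood mask is the
#' smoothed stack above the wall cutoff (Otsu by default), so the matrix
#' remains background (label 0); seeds are regional maxima of the
#' anisotropy-aware distance transform of that mask (cell centers), thinned
#' to `min_seed_sep_um`, or user-supplied points. Flood priority is the
#' smoothed intensity. Cells are grown under 6-adjacency: they are
#' wall-separated, so face contact suffices.
#'
#' @param boundary a brightfield [intensity_stack()].
#' @param config pipeline configuration (the `cells` block is used:
#'   `seed_sigma_um`, `min_seed_sep_um`, `wall_cutoff`).
#' @param seeds optional integer matrix of seed voxel coordinates
#'   (`z, y, x`, 1-based), one row per cell.
#' @return A cell [label_volume()].
#' @export
segment_cells <- function(boundary, config = default_config(), seeds = NULL) {
  if (!inherits(boundary, "intensity_stack")) stop("not an intensity_stack")
  config <- merge_config(config)
  cc <- config$cells
  cal <- calibration_of(boundary)
  sp <- cal_spacing_zyx(cal)
  dims <- dim(boundary)
  sig_vox <- cc$seed_sigma_um / sp
  smooth <- array(gauss3d_cpp(as.numeric(boundary), dims, sig_vox), dims)
  cutoff <- if (is.null(cc$wall_cutoff)) otsu_level(smooth) else cc$wall_cutoff
  mask <- smooth > cutoff
  if (is.null(seeds)) {
    # depth map for seeding: field faces count as boundary so the depth
    # peaks at 3D cell centers instead of forming ridges along open faces
    feat <- !mask
    feat[c(1, dims[1]), , ] <- TRUE
    feat[, c(1, dims[2]), ] <- TRUE
    feat[, , c(1, dims[3])] <- TRUE
    depth <- array(sqrt(edt_sq_cpp(feat, dims, sp)), dims)
    seeds <- find_local_maxima(depth, mask = mask, sp = sp,
                               min_sep_um = cc$min_seed_sep_um)
  } else {
    seeds <- as.matrix(seeds)
    if (ncol(seeds) != 3) stop("seeds must be a (z, y, x) coordinate matrix")
  }
  if (nrow(seeds) == 0) stop("zero seeds found for cell segmentation")
  seed_arr <- array(0L, dims)
  seed_arr[seeds] <- seq_len(nrow(seeds))
  if (!all(mask[seeds])) mask[seeds] <- TRUE   # user seeds always flood
  lab <- watershed_cpp(as.numeric(smooth), as.integer(seed_arr),
                       as.logical(mask), dims, 6L)
  label_volume(array(lab, dims), cal, kind = "cell")
}

#' Cells fully contained in the imaged field
#'
#' A cell is "integrated" when none of its voxels lies on any face of the
#' field bounding box (x/y faces and z faces alike). Per-cell metrics are
#' restricted to integrated cells, since partial cells bias the single-cell
#' volume.
#'
#' @param cells a cell [label_volume()].
#' @return Sorted integer vector of integrated cell ids.
#' @export
integrated_cells <- function(cells) {
  if (!inherits(cells, "label_volume")) stop("not a label_volume")
  d <- dim(cells)
  v <- unclass(cells)
  border <- c(v[1, , ], v[d[1], , ], v[, 1, ], v[, d[2], ],
              v[, , 1], v[, , d[3]])
  setdiff(positive_labels(cells), unique(border[border > 0]))
}

#' Assign droplets to cells by majority overlap
#'
#' Each droplet is assigned to the cell holding the plurality of its
#' voxels; ties are broken toward the smallest cell id. Droplets whose
#' voxels lie mostly (strict majority) on background are left unassigned.
#'
#' @param droplets a droplet [label_volume()].
#' @param cells a cell [label_volume()], same shape and calibration.
#' @return A data frame (class `cell_assignment`) with one row per droplet:
#'   `droplet_id`, `cell_id` (`NA` when unassigned), `n_vox`, `n_in_cell`,
#'   `frac_in_cell`.
#' @export
assign_droplets <- function(droplets, cells) {
  if (!inherits(droplets, "label_volume") || !inherits(cells, "label_volume"))
    stop("droplets and cells must be label_volumes")
  check_same_geometry(droplets, cells, "droplet and cell volumes")
  dv <- as.integer(droplets)
  cv <- as.integer(cells)
  idx <- dv > 0
  ids <- positive_labels(droplets)
  if (length(ids) == 0) {
    out <- data.frame(droplet_id = integer(0), cell_id = integer(0),
                      n_vox = integer(0), n_in_cell = integer(0),
                      frac_in_cell = numeric(0))
    class(out) <- c("cell_assignment", "data.frame")
    return(out)
  }
  d <- dv[idx]
  cl <- cv[idx]
  tot <- tabulate(d, nbins = max(ids))
  res <- vapply(split(cl, d), function(cc) {
    n <- length(cc)
    n_bg <- sum(cc == 0)
    if (n_bg * 2 > n) return(c(NA_real_, 0))
    tb <- tabulate(cc[cc > 0])
    best <- which.max(tb)                    # ties -> smallest id
    c(best, tb[best])
  }, numeric(2))
  ord_ids <- as.integer(colnames(res) %||% names(split(cl, d)))
  out <- data.frame(droplet_id = ord_ids,
                    cell_id = as.integer(res[1, ]),
                    n_vox = tot[ord_ids],
                    n_in_cell = as.integer(res[2, ]))
  out$frac_in_cell <- out$n_in_cell / out$n_vox
  out <- out[order(out$droplet_id), ]
  rownames(out) <- NULL
  class(out) <- c("cell_assignment", "data.frame")
  out
}
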