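#' Per-droplet geometry records
#'
#' One record per positive droplet label: voxel count, physical volume
#' (count times voxel volume), equivalent sphere diameter
#' `(6 V / pi)^(1/3)`, centroid in micrometers, and size-class flags.
#' "Large" droplets have equivalent diameter strictly above
#' `large_diam_um`; the small size class is volume strictly below
#' `small_class_um3` (boundary values are excluded from both classes).
#'
#' @param droplets a droplet [label_volume()].
#' @param assignment optional [assign_droplets()] result; when supplied,
#'   `cell_id` is joined in (`NA` for unassigned droplets).
#' @param large_diam_um large-droplet diameter threshold (default 5 um).
#' @param small_class_um3 small-class volume threshold (default 100 um^3).
#' @return A data frame with one row per droplet: `droplet_id`, `cell_id`,
#'   `voxel_count`, `volume_um3`, `eq_diameter_um`, `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um`, `is_large`, `is_small_class`,
#'   `touches_border`.
#' @export
droplet_records <- function(droplets, assignment = NULL,
                            large_diam_um = 5, small_class_um3 = 100) {
  if (!inherits(droplets, "label_volume")) stop("not a label_volume")
  cal <- calibration_of(droplets)
  vv <- voxel_volume(cal)
  sp <- cal_spacing_zyx(cal)
  dims <- dim(droplets)
  v <- as.integer(droplets)
  idx <- which(v > 0)
  ids <- positive_labels(droplets)
  if (length(ids) == 0) {
    out <- data.frame(droplet_id = integer(0), cell_id = integer(0),
                      voxel_count = integer(0), volume_um3 = numeric(0),
                      eq_diameter_um = numeric(0), centroid_z_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                      is_large = logical(0), is_small_class = logical(0),
                      touches_border = logical(0))
    return(out)
  }
  lab <- v[idx]
  co <- arrayInd(idx, dims)
  counts <- tabulate(lab, nbins = max(ids))[ids]
  # centroid of voxel centers, physical units ((i - 0.5) * pitch);
  # rowsum rows come back ordered by sort(unique(lab)) == ids
  sums <- rowsum(cbind((co[, 1] - 0.5) * sp[1],
                       (co[, 2] - 0.5) * sp[2],
                       (co[, 3] - 0.5) * sp[3]), lab)
  cent <- sums / counts
  on_border <- co[, 1] == 1 | co[, 1] == dims[1] |
    co[, 2] == 1 | co[, 2] == dims[2] |
    co[, 3] == 1 | co[, 3] == dims[3]
  border_ids <- unique(lab[on_border])
  vol <- counts * vv
  out <- data.frame(droplet_id = ids,
                    cell_id = NA_integer_,
                    voxel_count = counts,
                    volume_um3 = vol,
                    eq_diameter_um = (6 * vol / pi)^(1 / 3),
                    centroid_z_um = cent[, 1],
                    centroid_y_um = cent[, 2],
                    centroid_x_um = cent[, 3],
                    is_large = (6 * vol / pi)^(1 / 3) > large_diam_um,
                    is_small_class = vol < small_class_um3,
                    touches_border = ids %in% border_ids)
  if (!is.null(assignment))
    out$cell_id <- assignment$cell_id[match(out$droplet_id,
                                            assignment$droplet_id)]
  rownames(out) <- NULL
  out
}

#' Per-cell lipid metrics
#'
#' For every positive cell label: single-cell volume VSC (voxel count times
#' voxel volume), total assigned droplet volume VLD, the per-cell lipid
#' volume fraction VLD/VSC, droplet count TNLD, the number of large
#' droplets, and the integrated-cell flag.
#'
#' @param cells a cell [label_volume()].
#' @param records [droplet_records()] with `cell_id` filled in.
#' @param integrated integrated cell ids; defaults to
#'   [integrated_cells()]`(cells)`.
#' @return A data frame with one row per cell: `cell_id`, `voxel_count`,
#'   `vsc_um3`, `vld_um3`, `vld_vsc_ratio`, `tnld`, `n_large`,
#'   `is_integrated`.
#' @export
cell_records <- function(cells, records, integrated = NULL) {
  if (!inherits(cells, "label_volume")) stop("not a label_volume")
  if (is.null(integrated)) integrated <- integrated_cells(cells)
  vv <- voxel_volume(calibration_of(cells))
  ids <- positive_labels(cells)
  assigned <- records[!is.na(records$cell_id), , drop = FALSE]
  if (nrow(assigned) && !all(assigned$cell_id %in% ids))
    stop("droplet assigned to nonexistent cell id")
  v <- as.integer(cells)
  counts <- tabulate(v[v > 0], nbins = max(ids, 1))[ids]
  vld <- vapply(ids, function(id)
    sum(assigned$volume_um3[assigned$cell_id == id]), 0)
  tnld <- vapply(ids, function(id) sum(assigned$cell_id == id), 0L)
  n_large <- vapply(ids, function(id)
    sum(assigned$is_large[assigned$cell_id == id]), 0L)
  out <- data.frame(cell_id = ids,
                    voxel_count = counts,
                    vsc_um3 = counts * vv,
                    vld_um3 = vld,
                    vld_vsc_ratio = vld / (counts * vv),
                    tnld = tnld,
                    n_large = n_large,
                    is_integrated = ids %in% integrated)
  rownames(out) <- NULL
  out
}

#' Field-level summary
#'
#' VTSF is the physical volume of the full voxel grid; VTLD counts every
#' positive droplet voxel in the field, assigned or not ("total scanning
#' field" semantics). The mean inter-cell spacing is joined in when a
#' [cell_spacing()] result is supplied.
#'
#' @param droplets a droplet [label_volume()].
#' @param cells optional cell [label_volume()] (adds cell counts).
#' @param spacing optional [cell_spacing()] result.
#' @return A one-row data frame: `vtsf_um3`, `vtld_um3`, `vtld_vtsf_ratio`,
#'   `n_cells`, `n_integrated`, `mean_cell_spacing_um`, `n_spacing_pairs`.
#' @export
field_summary <- function(droplets, cells = NULL, spacing = NULL) {
  if (!inherits(droplets, "label_volume")) stop("not a label_volume")
  vv <- voxel_volume(calibration_of(droplets))
  vtsf <- prod(dim(droplets)) * vv
  vtld <- sum(unclass(droplets) > 0) * vv
  n_cells <- n_int <- NA_integer_
  if (!is.null(cells)) {
    check_same_geometry(droplets, cells, "droplet and cell volumes")
    n_cells <- length(positive_labels(cells))
    n_int <- length(integrated_cells(cells))
  }
  cs <- if (is.null(spacing)) NA_real_ else spacing$mean_spacing_um
  npairs <- if (is.null(spacing)) NA_integer_ else nrow(spacing$pairs)
  data.frame(vtsf_um3 = vtsf, vtld_um3 = vtld,
             vtld_vtsf_ratio = vtld / vtsf,
             n_cells = n_cells, n_integrated = n_int,
             mean_cell_spacing_um = cs, n_spacing_pairs = npairs)
}

#' Inter-cell spacing (cell interval space)
#'
#' For every unordered pair of cells whose minimum voxel-center-to-center
#' distance (physical units) is at most `max_gap_um`, the pair spacing is
#' that minimum distance minus one mean in-plane pitch (a surface
#' correction approximating edge-to-edge measurement), floored at zero.
#' The field-level CS is the mean over adjacent pairs.
#'
#' @param cells a cell [label_volume()] with at least 2 cells; with fewer,
#'   the mean is reported as missing (`NA`), not zero.
#' @param max_gap_um adjacency cutoff in micrometers (default 15).
#' @return A list with `mean_spacing_um` and a `pairs` data frame
#'   (`cell_a`, `cell_b`, `min_dist_um`, `spacing_um`).
#' @export
cell_spacing <- function(cells, max_gap_um = 15) {
  if (!inherits(cells, "label_volume")) stop("not a label_volume")
  cal <- calibration_of(cells)
  sp <- cal_spacing_zyx(cal)
  correction <- (cal[["dx_um"]] + cal[["dy_um"]]) / 2
  ids <- positive_labels(cells)
  pairs <- data.frame(cell_a = integer(0), cell_b = integer(0),
                      min_dist_um = numeric(0), spacing_um = numeric(0))
  if (length(ids) < 2) {
    return(list(mean_spacing_um = NA_real_, pairs = pairs))
  }
  dims <- dim(cells)
  v <- as.integer(cells)
  idx_by_id <- split(which(v > 0), v[v > 0])
  for (a_pos in seq_len(length(ids) - 1)) {
    a <- ids[a_pos]
    dsq <- edt_sq_cpp(v == a, dims, sp)
    for (b_pos in seq(a_pos + 1, length(ids))) {
      b <- ids[b_pos]
      dmin <- sqrt(min(dsq[idx_by_id[[as.character(b)]]]))
      if (dmin <= max_gap_um) {
        pairs <- rbind(pairs, data.frame(
          cell_a = a, cell_b = b, min_dist_um = dmin,
          spacing_um = max(0, dmin - correction)))
      }
    }
  }
  mean_cs <- if (nrow(pairs)) mean(pairs$spacing_um) else NA_real_
  list(mean_spacing_um = mean_cs, pairs = pairs)
}

#' Droplet size distribution and size classes
#'
#' Bins droplet volumes at the given interior edges (open-ended first and
#' last bins) and reports the large-droplet and small-class percentages,
#' plus a long-format table for external plotting.
#'
#' @param records [droplet_records()] output.
#' @param bin_edges_um3 increasing interior bin edges in um^3.
#' @param line_id optional line tag copied into the long table.
#' @return A list: `counts` (named per bin), `long` (one row per droplet:
#'   `line_id`, `cell_id`, `droplet_id`, `volume_um3`), `pct_large`,
#'   `pct_small_class` (percent; `NA` for an empty record set).
#' @export
size_distribution <- function(records, bin_edges_um3 = 100,
                              line_id = NA_character_) {
  if (is.unsorted(bin_edges_um3, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  edges <- c(-Inf, bin_edges_um3, Inf)
  labels <- paste0("[", head(edges, -1), ",", edges[-1], ")")
  bins <- findInterval(records$volume_um3, edges)
  counts <- tabulate(bins, nbins = length(edges) - 1)
  names(counts) <- labels
  long <- data.frame(line_id = rep(line_id, nrow(records)),
                     cell_id = records$cell_id,
                     droplet_id = records$droplet_id,
                     volume_um3 = records$volume_um3)
  n <- nrow(records)
  list(counts = counts,
       long = long,
       pct_large = if (n) 100 * sum(records$is_large) / n else NA_real_,
       pct_small_class = if (n) 100 * sum(records$is_small_class) / n else NA_real_)
}
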