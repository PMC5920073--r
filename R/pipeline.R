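#' Quantify one field end to end
#'
#' Runs the full measurement pipeline on a fluorescence stack plus a cell
#' source: droplet segmentation, cell segmentation (or supplied labels),
#' droplet-to-cell assignment, per-droplet and per-cell records, inter-cell
#' spacing and the field summary. Per-cell metrics are restricted to
#' integrated cells; the field-level droplet volume uses every droplet.
#'
#' @param fluor fluorescence [intensity_stack()].
#' @param cells either a cell [label_volume()] (pre-made labels, the
#'   `label_file` source) or a brightfield [intensity_stack()] to segment.
#' @param config pipeline configuration, see [default_config()].
#' @return List of class `ld3d_quantification`: `droplet_labels`,
#'   `cell_labels`, `assignment`, `droplets` (records), `cells` (records),
#'   `spacing`, `field` (one-row summary), `config`.
#' @export
quantify_field <- function(fluor, cells, config = default_config()) {
  config <- merge_config(config)
  droplet_labels <- segment_droplets(fluor, config)
  cell_labels <- if (inherits(cells, "label_volume")) {
    cells
  } else if (inherits(cells, "intensity_stack")) {
    segment_cells(cells, config)
  } else {
    stop("cells must be a label_volume or a brightfield intensity_stack")
  }
  check_same_geometry(droplet_labels, cell_labels,
                      "fluorescence and cell volumes")
  assignment <- assign_droplets(droplet_labels, cell_labels)
  mx <- config$metrics
  records <- droplet_records(droplet_labels, assignment,
                             large_diam_um = mx$large_diam_um,
                             small_class_um3 = mx$small_class_um3)
  integrated <- integrated_cells(cell_labels)
  cellrec <- cell_records(cell_labels, records, integrated)
  spacing <- if (length(positive_labels(cell_labels)) >= 2)
    cell_spacing(cell_labels, mx$max_gap_um)
  else
    list(mean_spacing_um = NA_real_,
         pairs = data.frame(cell_a = integer(0), cell_b = integer(0),
                            min_dist_um = numeric(0), spacing_um = numeric(0)))
  field <- field_summary(droplet_labels, cell_labels, spacing)
  structure(list(droplet_labels = droplet_labels, cell_labels = cell_labels,
                 assignment = assignment, droplets = records,
                 cells = cellrec, spacing = spacing, field = field,
                 config = config),
            class = "ld3d_quantification")
}

#' Write the tabular outputs of a quantification
#'
#' Writes `droplets.csv`, `cells.csv`, `field_summary.csv`,
#' `spacing_pairs.csv` and the resolved `config.json` into `dir`.
#'
#' @param q an `ld3d_quantification` from [quantify_field()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quantification <- function(q, dir) {
  stopifnot(inherits(q, "ld3d_quantification"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(q$droplets, file.path(dir, "droplets.csv"), row.names = FALSE)
  write.csv(q$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(q$field, file.path(dir, "field_summary.csv"), row.names = FALSE)
  write.csv(q$spacing$pairs, file.path(dir, "spacing_pairs.csv"),
            row.names = FALSE)
  write_config(q$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Simulate a field and write it to disk
#'
#' Runs [generate_field()] and writes the two channels, the truth labels
#' and the truth droplet table into `dir` (TIFF + CSV via the stack I/O
#' layer), together with the generating spec as JSON.
#'
#' @param spec a [synthetic_spec()] or preset name.
#' @param dir output directory.
#' @return The in-memory field (list), invisibly.
#' @export
simulate_field <- function(spec, dir) {
  if (is.character(spec)) spec <- preset_spec(spec)
  field <- generate_field(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(field$fluorescence, file.path(dir, "fluorescence.tif"))
  write_stack(field$brightfield, file.path(dir, "brightfield.tif"))
  write_label_volume(field$truth$cell_labels, file.path(dir, "truth_cells.tif"))
  write_label_volume(field$truth$droplet_labels,
                     file.path(dir, "truth_droplets.tif"))
  write.csv(field$truth$droplets, file.path(dir, "truth_droplets.csv"),
            row.names = FALSE)
  spec_json <- unclass(spec)
  spec_json$cal <- as.list(unclass(spec$cal))
  jsonlite::write_json(spec_json, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(field)
}

#' Simulate and quantify a panel of lines, then compare groups
#'
#' Generates `n_replicates` fields per line (replicate fields of the same
#' line differ only in seed, echoing repeated imaging fields of one
#' genotype), quantifies each against its truth cell labels, and compares
#' the groups on the per-cell lipid fraction (VLD/VSC over integrated
#' cells), droplet count per cell (TNLD), field lipid fraction
#' (VTLD/VTSF) and mean inter-cell spacing (CS). Line summaries are
#' mean +/- SD over replicate fields; the group test runs on line means.
#'
#' @param ho_specs,lo_specs lists of [synthetic_spec()]s, one per line.
#' @param config pipeline configuration.
#' @param n_replicates fields per line (default 3).
#' @return List: `fields` (per-field metric table), `lines` (per-line
#'   means), `summaries` (stacked [summarize_line()] rows over replicate
#'   fields), `comparisons` (stacked [compare_groups()] rows, one per
#'   metric, on line means).
#' @export
compare_synthetic_lines <- function(ho_specs, lo_specs,
                                    config = default_config(),
                                    n_replicates = 3) {
  metrics <- c("vld_vsc_pct", "tnld", "vtld_vtsf_pct", "cs_um")
  measure_field <- function(spec, line_id, group, rep) {
    spec$seed <- spec$seed * 10 + rep - 1
    field <- generate_field(spec)
    q <- quantify_field(field$fluorescence, field$truth$cell_labels, config)
    cells_int <- q$cells[q$cells$is_integrated, , drop = FALSE]
    data.frame(line_id = line_id, group = group, replicate = rep,
               vld_vsc_pct = 100 * mean(cells_int$vld_vsc_ratio),
               tnld = mean(cells_int$tnld),
               vtld_vtsf_pct = 100 * q$field$vtld_vtsf_ratio,
               cs_um = q$spacing$mean_spacing_um)
  }
  specs <- c(ho_specs, lo_specs)
  tags <- c(sprintf("HO%d", seq_along(ho_specs)),
            sprintf("LO%d", seq_along(lo_specs)))
  groups <- rep(c("HO", "LO"), c(length(ho_specs), length(lo_specs)))
  fields <- do.call(rbind, unlist(lapply(seq_along(specs), function(i)
    lapply(seq_len(n_replicates), function(r)
      measure_field(specs[[i]], tags[i], groups[i], r))),
    recursive = FALSE))
  lines <- do.call(rbind, lapply(unique(fields$line_id), function(l) {
    sub <- fields[fields$line_id == l, , drop = FALSE]
    out <- data.frame(line_id = l, group = sub$group[1])
    for (m in metrics) out[[m]] <- mean(sub[[m]])
    out
  }))
  summaries <- do.call(rbind, unlist(lapply(unique(fields$line_id),
    function(l) {
      sub <- fields[fields$line_id == l, , drop = FALSE]
      lapply(metrics, function(m)
        summarize_line(sub[[m]], l, sub$group[1], m))
    }), recursive = FALSE))
  comparisons <- do.call(rbind, lapply(metrics, function(m)
    compare_groups(lines[[m]][lines$group == "HO"],
                   lines[[m]][lines$group == "LO"], metric = m,
                   method = merge_config(config)$report$test)))
  list(fields = fields, lines = lines, summaries = summaries,
       comparisons = comparisons)
}

#' Per-line specs for the phenotype contrast
#'
#' Three high-oil-like and three low-oil-like line specs whose droplet
#' counts and wall widths bracket the group presets (within-group spread
#' echoes the spread seen between real breeding lines), with line-specific
#' seeds derived from `seed`.
#'
#' @param seed base seed; line seeds are `seed * 100 + line index`.
#' @param ... shared overrides passed to every [preset_spec()] call.
#' @return List with `ho` and `lo` lists of specs.
#' @export
contrast_line_specs <- function(seed = 1, ...) {
  ho_n <- c(60, 70, 80)
  ho_wall <- c(3.6, 4.0, 4.4)
  lo_n <- c(26, 30, 34)
  lo_wall <- c(5.6, 6.0, 6.4)
  ho <- lapply(1:3, function(i)
    preset_spec("ho_like", droplets_per_cell = ho_n[i], wall_um = ho_wall[i],
                seed = seed * 100 + i, ...))
  lo <- lapply(1:3, function(i)
    preset_spec("lo_like", droplets_per_cell = lo_n[i], wall_um = lo_wall[i],
                seed = seed * 100 + 3 + i, ...))
  list(ho = ho, lo = lo)
}
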