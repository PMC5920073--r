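#!/usr/bin/env Rscript
# Quantify every simulated field from its files: segment droplets from the
# fluorescence stack, take cells from the truth label file (the pipeline's
# `label_file` source; pass --cells brightfield to re-segment cells by
# watershed instead), assign droplets to cells and write the per-field
# tables (droplets.csv, cells.csv, field_summary.csv, spacing_pairs.csv).
#
# Usage: Rscript analysis/02_quantify.R [--fields scratch/fields]
#                                       [--cells label_file|brightfield]

suppressPackageStartupMessages(library(ld3d))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
root <- get_arg("--fields", "scratch/fields")
cell_source <- match.arg(get_arg("--cells", "label_file"),
                         c("label_file", "brightfield"))

manifest <- read.csv(file.path(root, "manifest.csv"),
                     stringsAsFactors = FALSE)
config <- merge_config(list(cells = list(source = cell_source)))

for (i in seq_len(nrow(manifest))) {
  dir <- manifest$field_dir[i]
  message(sprintf("quantifying %s (%s)", dir, manifest$line_id[i]))
  fluor <- read_stack(file.path(dir, "fluorescence.tif"))
  cells <- if (cell_source == "label_file") {
    read_label_volume(file.path(dir, "truth_cells.tif"))
  } else {
    read_stack(file.path(dir, "brightfield.tif"), channel = "brightfield")
  }
  q <- quantify_field(fluor, cells, config)
  write_quantification(q, dir)
  int_cells <- q$cells[q$cells$is_integrated, , drop = FALSE]
  message(sprintf(
    "  VTLD/VTSF %.2f%% | mean VLD/VSC %.2f%% | mean TNLD %.1f | CS %.2f um",
    100 * q$field$vtld_vtsf_ratio, 100 * mean(int_cells$vld_vsc_ratio),
    mean(int_cells$tnld), q$spacing$mean_spacing_um))
}
message("done")
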