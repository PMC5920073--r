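#!/usr/bin/env Rscript
# Aggregate the per-field tables into line-level summaries (mean +/- SD
# over replicate fields) and the high-oil vs low-oil group comparison
# (Welch test on line means) for the four headline metrics: per-cell
# lipid fraction VLD/VSC, droplets per cell TNLD, field fraction
# VTLD/VTSF and inter-cell spacing CS. Also exports the violin-ready
# long-format droplet size table.
#
# Usage: Rscript analysis/03_compare.R [--fields scratch/fields]
#                                      [--out results/report]

suppressPackageStartupMessages(library(ld3d))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
root <- get_arg("--fields", "scratch/fields")
out <- get_arg("--out", "results/report")

manifest <- read.csv(file.path(root, "manifest.csv"),
                     stringsAsFactors = FALSE)
metrics <- c("vld_vsc_pct", "tnld", "vtld_vtsf_pct", "cs_um")

fields <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  dir <- manifest$field_dir[i]
  cells <- read.csv(file.path(dir, "cells.csv"))
  fs <- read.csv(file.path(dir, "field_summary.csv"))
  int_cells <- cells[cells$is_integrated, , drop = FALSE]
  data.frame(line_id = manifest$line_id[i], group = manifest$group[i],
             replicate = manifest$replicate[i],
             vld_vsc_pct = 100 * mean(int_cells$vld_vsc_ratio),
             tnld = mean(int_cells$tnld),
             vtld_vtsf_pct = 100 * fs$vtld_vtsf_ratio,
             cs_um = fs$mean_cell_spacing_um)
}))

summaries <- do.call(rbind, unlist(lapply(unique(fields$line_id),
  function(l) {
    sub <- fields[fields$line_id == l, , drop = FALSE]
    lapply(metrics, function(m) summarize_line(sub[[m]], l, sub$group[1], m))
  }), recursive = FALSE))

lines <- do.call(rbind, lapply(unique(fields$line_id), function(l) {
  sub <- fields[fields$line_id == l, , drop = FALSE]
  out <- data.frame(line_id = l, group = sub$group[1])
  for (m in metrics) out[[m]] <- mean(sub[[m]])
  out
}))
comparisons <- do.call(rbind, lapply(metrics, function(m)
  compare_groups(lines[[m]][lines$group == "HO"],
                 lines[[m]][lines$group == "LO"], metric = m)))

sizes_long <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  drops <- read.csv(file.path(manifest$field_dir[i], "droplets.csv"))
  data.frame(line_id = manifest$line_id[i], group = manifest$group[i],
             cell_id = drops$cell_id, volume_um3 = drops$volume_um3)
}))

export_reports(summaries, comparisons, out, sizes_long = sizes_long)

message("line summaries (mean over replicate fields):")
for (i in seq_len(nrow(lines)))
  message(sprintf(
    "  %s (%s): VLD/VSC %.2f%% | TNLD %.1f | VTLD/VTSF %.2f%% | CS %.2f um",
    lines$line_id[i], lines$group[i], lines$vld_vsc_pct[i], lines$tnld[i],
    lines$vtld_vtsf_pct[i], lines$cs_um[i]))
message("group comparison (Welch on line means):")
for (i in seq_len(nrow(comparisons)))
  message(sprintf("  %-14s HO %.3f vs LO %.3f, t = %.2f, p = %.4f",
                  comparisons$metric[i], comparisons$mean_ho[i],
                  comparisons$mean_lo[i], comparisons$statistic[i],
                  comparisons$p_value[i]))
message(sprintf("tables written under %s", out))
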