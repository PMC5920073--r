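#!/usr/bin/env Rscript
# Simulate the study's imaging panel: three high-oil-like and three
# low-oil-like breeding lines, three confocal fields each. Every field is
# written to disk (fluorescence + bright-field TIFF stacks, truth labels,
# truth droplet tables) so the quantification step can run purely from
# files, exactly as it would on real acquisitions.
#
# Usage: Rscript analysis/01_simulate.R [--seed N] [--out scratch/fields]

suppressPackageStartupMessages(library(ld3d))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_root <- get_arg("--out", "scratch/fields")
n_replicates <- 3

specs <- contrast_line_specs(seed = seed)
manifest <- data.frame(line_id = character(0), group = character(0),
                       replicate = integer(0), field_dir = character(0))

for (group in c("ho", "lo")) {
  for (i in seq_along(specs[[group]])) {
    for (rep in seq_len(n_replicates)) {
      spec <- specs[[group]][[i]]
      spec$seed <- spec$seed * 10 + rep - 1
      line_id <- sprintf("%s%d", toupper(group), i)
      dir <- file.path(out_root, sprintf("%s_rep%d", line_id, rep))
      message(sprintf("simulating %s replicate %d -> %s", line_id, rep, dir))
      field <- simulate_field(spec, dir)
      manifest <- rbind(manifest, data.frame(
        line_id = line_id, group = toupper(group), replicate = rep,
        field_dir = dir))
      message(sprintf("  %d cells, %d droplets, true lipid fraction %.2f%%",
                      spec$n_cells, nrow(field$truth$droplets),
                      100 * field$truth$true_field_fraction))
    }
  }
}

write.csv(manifest, file.path(out_root, "manifest.csv"), row.names = FALSE)
message(sprintf("wrote %d fields and manifest.csv under %s",
                nrow(manifest), out_root))
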