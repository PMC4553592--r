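#!/usr/bin/env Rscript
# Stage 3: trigger-site maps and the ts/nts partition.
#
# Pools the wave trigger registry into per-phase trigger-activity maps
# (source square + its 8 neighbors, value 1.0 each), scales each map to
# its phase maximum, and partitions the active (non-mouth-zone) squares
# into trigger sites (activity > 0) and non-trigger sites.
#
# Reads:  results/run_config.yaml, results/gt_registry.csv
# Writes: results/trigger_map_<phase>.{csv,png}, results/partition.csv

suppressPackageStartupMessages(library(beeshimmer))

config <- read_run_config("results/run_config.yaml")
registry <- read_trigger_registry("results/gt_registry.csv")
grid <- build_grid(c(config$scene$grid_rows * config$scene$square_px,
                     config$scene$grid_cols * config$scene$square_px),
                   config$scene$square_px)
active <- apply_mask(grid, region_mask(
  as.data.frame(config$scene$mouth_zone$squares), "mouth_zone"))

for (ph in names(config$phases)) {
  iv <- config$phases[[ph]]
  reg <- registry[registry$start_frame >= iv[1] &
                    registry$start_frame <= iv[2], , drop = FALSE]
  m <- scale_map(pool_trigger_activity(reg, grid))
  cat(sprintf("%-7s %2d trigger entries, %3d trigger squares, max activity %g\n",
              ph, nrow(reg), sum(m$activity > 0), max(m$activity)))
  write.table(m$activity, sprintf("results/trigger_map_%s.csv", ph),
              sep = ",", row.names = FALSE, col.names = FALSE)
  write_heatmap_png(m$scaled, sprintf("results/trigger_map_%s.png", ph))
}

# the cohort comparison pools all waves of the run: a square is a trigger
# site if any registered wave was launched from its neighborhood
m_all <- pool_trigger_activity(registry, grid)
part <- partition_cohorts(m_all, active)
cat("pooled partition:", nrow(part$ts), "ts squares,",
    nrow(part$nts), "nts squares\n")
partition <- rbind(data.frame(part$ts, cohort = "ts"),
                   data.frame(part$nts, cohort = "nts"))
write.csv(partition, "results/partition.csv", row.names = FALSE)
cat("written: results/trigger_map_<phase>.{csv,png}, results/partition.csv\n")
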