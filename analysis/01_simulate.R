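#!/usr/bin/env Rscript
# Stage 1: build the synthetic nest experiment.
#
# One 90 s scene at 50 fps on a 24 x 36 square grid (4 px per square):
# a quiescent preP phase, a presentation window in which six shimmering
# waves are launched from three trigger sites, and a postP phase. The
# trigger-site neighborhoods host a flicker cohort of higher amplitude
# (dlum 8) than the remaining surface squares (dlum 5) — the designed
# ts > nts intensity contrast. A small mouth zone produces sustained
# motion that must not be counted as flickering.
#
# Writes: results/run_config.yaml, results/gt_{events,registry}.csv

suppressPackageStartupMessages(library(beeshimmer))
dir.create("results", showWarnings = FALSE)

ROWS <- 24; COLS <- 36
FPS <- 50; N_FRAMES <- 4500
TRIGGERS <- list(c(6, 9), c(12, 24), c(18, 15))
WAVE_FRAMES <- c(1520, 1650, 1780, 1910, 2040, 2170)

grid <- build_grid(c(ROWS * 4, COLS * 4), 4)
ts_sq <- unique(do.call(rbind, lapply(TRIGGERS, function(s)
  assign_trigger_site(s, grid)[, c("row", "col")])))
all_sq <- grid_squares(grid)
mouth <- all_sq[all_sq$row >= 21 & all_sq$col <= 4, ]
key <- function(d) paste(d$row, d$col)
rest <- all_sq[!(key(all_sq) %in% c(key(ts_sq), key(mouth))), ]
set.seed(100)
nts_sq <- rest[sample(nrow(rest), 200), ]

config <- list(
  scene = list(
    grid_rows = ROWS, grid_cols = COLS, square_px = 4, fps = FPS,
    n_frames = N_FRAMES, noise_sd = 0.5,
    mouth_zone = list(squares = mouth, amplitude = 10),
    cohorts = list(
      cohort_spec(ts_sq, flicker_rate = 0.25, amplitude_mean = 8,
                  amplitude_sd = 1.5, label = "ts"),
      cohort_spec(nts_sq, flicker_rate = 0.25, amplitude_mean = 5,
                  amplitude_sd = 1.5, label = "nts")),
    waves = lapply(seq_along(WAVE_FRAMES), function(i)
      wave_spec(TRIGGERS[[(i - 1) %% 3 + 1]], WAVE_FRAMES[i], speed = 2,
                participation_prob = 0.9, flip_amplitude = 15))),
  filter = list(detect_threshold = 2.0, max_duration_frames = 3,
                min_gap_s = 1.0),
  shimmer = list(frac_threshold = 0.15, min_len_frames = 3),
  phases = list(preP = c(0, 1499), P = c(1500, 2259),
                postP1 = c(2260, 4498)),
  seed = 2012
)
write_run_config(config, "results/run_config.yaml")

sc <- do.call(scene_config, c(config$scene, list(seed = config$seed)))
gt <- simulate_ground_truth(sc)
write_ground_truth(gt, "results/gt")

cat("scene:", ROWS, "x", COLS, "squares,", N_FRAMES, "frames at", FPS, "fps\n")
cat("ground-truth events by kind:\n")
print(table(gt$events$kind))
cat("flicker events by cohort:\n")
print(table(gt$events$cohort[gt$events$kind == "flicker"]))
cat("trigger registry:", nrow(gt$trigger_registry), "waves from",
    length(unique(paste(gt$trigger_registry$row, gt$trigger_registry$col))),
    "sites\n")
cat("written: results/run_config.yaml, results/gt_events.csv,",
    "results/gt_registry.csv\n")
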