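#!/usr/bin/env Rscript
# Stage 2: motion fields and flicker detection.
#
# Re-renders the configured scene deterministically, pools the frame
# differences onto the assessment grid, masks shimmering episodes found
# from the simultaneous-activity fraction, and applies the interval
# filter (dlum > 2.0 for at most 3 frames, 1 s refractory merge).
#
# Reads:  results/run_config.yaml
# Writes: results/events_{raw,filtered}.csv, results/episodes.csv

suppressPackageStartupMessages(library(beeshimmer))

config <- read_run_config("results/run_config.yaml")
sc_args <- config$scene
sc_args$seed <- config$seed
sc_args$cohorts <- lapply(sc_args$cohorts, function(co) {
  co$squares <- as.data.frame(co$squares); do.call(cohort_spec, co) })
sc_args$waves <- lapply(sc_args$waves, function(w) do.call(wave_spec, w))
sc_args$mouth_zone$squares <- as.data.frame(sc_args$mouth_zone$squares)
sc <- do.call(scene_config, sc_args)

r <- render_frames(sc)
cat("rendered", dim(r$stack)[3], "frames of",
    dim(r$stack)[1], "x", dim(r$stack)[2], "px\n")

series <- square_series(r$stack, r$grid)
cfg <- do.call(event_filter_config,
               c(config$filter, list(fps = config$scene$fps)))
frac <- activity_fraction(series, cfg$detect_threshold)
episodes <- detect_shimmer_episodes(frac, config$shimmer$frac_threshold,
                                    config$shimmer$min_len_frames)
cat("shimmer episodes:", nrow(episodes), " frames masked:",
    sum(episodes$end_frame - episodes$start_frame + 1), "\n")

events <- detect_events_all(series, r$grid, cfg)
active <- apply_mask(r$grid, region_mask(
  as.data.frame(config$scene$mouth_zone$squares), "mouth_zone"))
kept <- filter_events(events, episodes, active)
cat("events detected:", nrow(events), " after filtering:", nrow(kept), "\n")

gt <- read_ground_truth("results/gt")
gt_fl <- gt$events[gt$events$kind == "flicker", ]
# flickers are only claimed detectable outside shimmering episodes
clear <- rep(TRUE, nrow(gt_fl))
for (i in seq_len(nrow(episodes))) {
  clear <- clear & !(gt_fl$onset_frame + gt_fl$duration_frames - 1 >=
                       episodes$start_frame[i] &
                       gt_fl$onset_frame <= episodes$end_frame[i])
}
okey <- function(d) paste(d$row, d$col, d$onset_frame)
cat(sprintf("flicker onset recall outside episodes: %.4f (%d of %d truth events)\n",
            mean(okey(gt_fl[clear, ]) %in% okey(kept)), sum(clear),
            nrow(gt_fl)))

write_events(events, "results/events_raw.csv")
write_events(kept, "results/events_filtered.csv")
write.csv(episodes, "results/episodes.csv", row.names = FALSE)
cat("written: results/events_raw.csv, results/events_filtered.csv,",
    "results/episodes.csv\n")
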