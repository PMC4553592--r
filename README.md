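# beeshimmer

Quantification of **flickering** and **shimmering** in Giant Honey Bee
(*Apis dorsata*) nest-surface videos.

Giant Honey Bees nest in the open, as a single comb covered by a curtain of
bees. Under threat the curtain produces *shimmering*: Mexican-wave-like
cascades of dorso-ventral abdomen flips sweeping across the nest. Under
quiescence individual surface bees show *flickering*: brief, seemingly
stochastic abdomen flips. A central question is whether flickering is a
precursor state of shimmering — whether the squares of nest surface that
launch shimmering waves (*trigger sites*, ts) flicker more intensely than
the rest (*non-trigger sites*, nts), and whether arousal recruits
additional trigger cohorts.

`beeshimmer` implements the video-computation side of that analysis for
researchers working on collective behavior in social insects:

1. **Motion fields** — consecutive video frames are subtracted pixel-wise;
   the unsigned luminance change Δlum (0 = motionless, 255 = maximal) is
   pooled onto a lattice of bee-sized *test squares* (15 mm side length),
   giving one Δlum time series per square.
2. **Flicker detection** — a flickering event is a run of square-level
   Δlum > 2.0 lasting at most 3 frames (60 ms at 50 fps); longer runs are
   sustained motion (fanning, walking) and are rejected. Events on one
   square closer than 1 s merge into the earlier event. Frames in which a
   large fraction of squares move simultaneously are flagged as shimmering
   episodes and masked, and mouth-zone squares are excluded.
3. **Trigger-site maps** — each registered wave source square and its 8
   neighbors receive trigger-activity 1.0; pooled maps are scaled to their
   per-phase maximum, and the active squares are partitioned into ts
   (activity > 0) and nts cohorts.
4. **Cohort statistics** — per square, flickering rate (events/s) and
   intensity `fI = Σ Δlum / t_ref`; relF occupancy fractions; compilation
   into 30 rate classes of 0.03 s⁻¹ with per-cohort mean fI ± SEM;
   exponential fits `y = a·e^(b·x)` to the class means (log-linear least
   squares); Spearman rank correlation of rate vs intensity; and the
   per-class sign comparison Δ_fI = fI_ts − fI_nts tested with
   χ² = (n₊ − n₋)²/(n₊ + n₋), df = 1.

Because no field footage is publicly deposited, the package ships a
**synthetic nest-video generator** (`scene_config()`, `render_frames()`)
that renders one bee ellipse per square and translates ground-truth events
— renewal-process flickers, Chebyshev-expanding waves, sustained mouth-zone
motion, Gaussian sensor noise — into exact frame-difference signatures, so
every stage can be validated against known truth.

## Worked example

```r
library(beeshimmer)

# a 20 s synthetic scene: 8 x 8 squares, all flickering at 0.2 events/s
sq <- expand.grid(col = 0:7, row = 0:7)[, c("row", "col")]
scene <- scene_config(8, 8, square_px = 6, fps = 50, n_frames = 1000,
                      noise_sd = 0.5,
                      cohorts = list(cohort_spec(sq, flicker_rate = 0.2,
                                                 amplitude_mean = 8,
                                                 amplitude_sd = 2)),
                      seed = 7)
r <- render_frames(scene)
series <- square_series(r$stack, r$grid)
events <- detect_events_all(series, r$grid, event_filter_config(fps = 50))

nrow(r$ground_truth$events)   # 266 ground-truth flickers
nrow(events)                  # 266 detected
head(events, 3)
#>   row col onset_frame duration_frames peak_dlum  sum_dlum
#> 1   0   0           9               1  3.833333  3.833333
#> 2   0   0         384               1 12.833333 12.833333
#> 3   0   0         776               1  7.194444  7.194444

# rate and intensity per square, with a designed two-cohort split
part <- cohort_partition(sq[1:32, ], sq[33:64, ])
rec <- rate_intensity_records(events, part, t_ref = 20)
summary(rec$rate_hz)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.1000  0.1500  0.2000  0.2078  0.2500  0.4000

act <- rec[rec$n_events > 0, ]
s <- spearman_rate_intensity(act$rate_hz, act$fI)
sprintf("rho = %.3f, P = %.2g", s$rho, s$p_value)
#> "rho = 0.718, P = 2.4e-11"
```

Every detected event carries its square, onset (0-based difference-frame
index), duration in frames, and peak/summed Δlum; the summed Δlum per
square divided by the reference time is the flickering intensity fI.

## Analysis workflow

The `analysis/` directory holds a four-stage narrative workflow over the
package, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # scene + ground truth + wave registry
Rscript analysis/02_detect.R        # motion series, episodes, flicker events
Rscript analysis/03_map_triggers.R  # per-phase trigger maps, ts/nts partition
Rscript analysis/04_cohort_stats.R  # relF, rate classes, fits, sign/chi-square
```

The simulated experiment has a quiescent preP phase, a presentation phase
with six shimmering waves from three trigger sites, and a postP phase; the
trigger neighborhoods carry a higher flicker amplitude (8 vs 5 Δlum), and
stage 4 recovers that contrast as a majority of positive Δ_fI classes.

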