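cfg50 <- event_filter_config(fps = 50)

test_that("supra-threshold runs of 1-3 frames become events", {
  ev <- detect_events(c(0, 0, 3, 0, 0), cfg50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 2)
  expect_equal(ev$duration_frames, 1)
  expect_equal(ev$peak_dlum, 3)

  # exactly at the threshold is NOT an event (strict inequality)
  expect_equal(nrow(detect_events(c(0, 2.0, 0), cfg50)), 0)
  expect_equal(nrow(detect_events(c(0, 2.01, 0), cfg50)), 1)
})

test_that("runs longer than three frames are sustained motion, not flicker", {
  expect_equal(nrow(detect_events(c(0, 5, 5, 5, 5, 0), cfg50)), 0)
  ev3 <- detect_events(c(0, 5, 5, 5, 0), cfg50)
  expect_equal(ev3$duration_frames, 3)
})

test_that("the three-frame bound corresponds to 60 ms at 50 fps", {
  expect_equal(cfg50$max_duration_frames / cfg50$fps * 1000, 60)
})

test_that("detection matches the exhaustive run-length oracle", {
  set.seed(11)
  no_gap <- event_filter_config(min_gap_s = 0, fps = 50)
  for (i in 1:50) {
    tr <- round(rexp(60, 1 / 2), 1)
    got <- detect_events(tr, no_gap)
    ref <- naive_runs(tr, 2.0, 3)
    expect_equal(got$onset_frame, ref$onset)
    expect_equal(got$duration_frames, ref$len)
    expect_equal(got$sum_dlum, ref$sum)
  }
})

test_that("raising the detection threshold never increases the count of
           flicker-like transients", {
  # on flicker-like traces (isolated 1-3 frame pulses separated by zeros)
  # the event count is non-increasing in the threshold; note this does not
  # hold for arbitrary traces, where a higher threshold can split a
  # sustained (rejected) run into short accepted ones
  set.seed(12)
  for (i in 1:10) {
    tr <- rep(0, 400)
    onsets <- seq(3, 380, by = 8)
    for (o in onsets) {
      d <- sample(1:3, 1)
      tr[o:(o + d - 1)] <- round(rexp(d, 1 / 4), 1)
    }
    counts <- sapply(c(0.5, 1, 2, 4, 8, 16), function(th) {
      cfg <- event_filter_config(detect_threshold = th, min_gap_s = 0,
                                 fps = 50)
      nrow(detect_events(tr, cfg))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("onsets within the refractory window merge into the earlier event", {
  tr <- rep(0, 100)
  tr[11] <- 5   # onset 10
  tr[41] <- 4   # onset 40, within 50 frames (1 s at 50 fps)
  ev <- detect_events(tr, cfg50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 10)
  expect_equal(ev$sum_dlum, 9)   # the repeat is folded in
  expect_equal(ev$peak_dlum, 5)

  tr[41] <- 0; tr[72] <- 4  # onset 71, gap 61 > 50 frames
  ev2 <- detect_events(tr, cfg50)
  expect_equal(nrow(ev2), 2)
})

test_that("shimmer episodes are found from simultaneous activity", {
  expect_equal(nrow(detect_shimmer_episodes(rep(0, 50))), 0)

  # degenerate bound: zero threshold spans everything
  all_ep <- detect_shimmer_episodes(runif(20), frac_threshold = 0)
  expect_equal(nrow(all_ep), 1)
  expect_equal(all_ep$start_frame, 0)
  expect_equal(all_ep$end_frame, 19)

  f <- rep(0.02, 200); f[101:141] <- 0.4
  ep <- detect_shimmer_episodes(f, frac_threshold = 0.2)
  expect_equal(nrow(ep), 1)
  expect_true(ep$start_frame <= 100 && ep$end_frame >= 140)

  # short blips below min_len_frames are ignored
  g <- rep(0, 50); g[10] <- 1
  expect_equal(nrow(detect_shimmer_episodes(g, 0.2, min_len_frames = 3)), 0)
  expect_error(detect_shimmer_episodes(c(0.5, 1.2)), "0, 1")
})

test_that("a synthetic wave produces one maskable shimmer episode", {
  sc <- scene_config(8, 8, square_px = 4, fps = 50, n_frames = 60,
                     waves = list(wave_spec(c(4, 4), start_frame = 20,
                                            speed = 1, flip_amplitude = 15)),
                     seed = 21)
  r <- render_frames(sc)
  ser <- square_series(r$stack, r$grid)
  frac <- activity_fraction(ser, 2.0)
  ep <- detect_shimmer_episodes(frac, frac_threshold = 0.15)
  expect_equal(nrow(ep), 1)
  wave_onsets <- r$ground_truth$events$onset_frame
  # the episode engulfs the wave sweep (the first ring or two may fall
  # below the simultaneity fraction)
  expect_true(ep$start_frame >= min(wave_onsets))
  expect_true(ep$start_frame <= min(wave_onsets) + 2)
  expect_true(ep$end_frame >= max(wave_onsets))
})

test_that("event filtering removes masked squares and episode overlaps", {
  ev <- data.frame(row = c(0, 0, 1), col = c(0, 1, 1),
                   onset_frame = c(5, 20, 35), duration_frames = c(1, 2, 3),
                   peak_dlum = 5, sum_dlum = 5)
  # identity with no filters
  expect_equal(filter_events(ev), ev)

  ep <- data.frame(start_frame = 19, end_frame = 25)
  kept <- filter_events(ev, ep)
  expect_equal(kept$onset_frame, c(5, 35))

  active <- data.frame(row = c(0, 0), col = c(0, 1))  # square (1,1) masked
  kept2 <- filter_events(ev, ep, active)
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$onset_frame, 5)

  # idempotence
  expect_equal(filter_events(kept2, ep, active), kept2)
  # an event whose tail reaches into an episode is removed too
  ev_edge <- data.frame(row = 0, col = 0, onset_frame = 17,
                        duration_frames = 3, peak_dlum = 5, sum_dlum = 5)
  expect_equal(nrow(filter_events(ev_edge, ep)), 0)
})

test_that("flickers overlapping a wave episode are exactly the ones removed", {
  sq <- all_squares(8, 8)
  sc <- scene_config(8, 8, square_px = 4, fps = 50, n_frames = 1500,
                     cohorts = list(cohort_spec(sq, 0.15, 8, 1)),
                     waves = list(wave_spec(c(4, 4), 700, speed = 1,
                                            flip_amplitude = 15)),
                     seed = 31)
  r <- render_frames(sc)
  ser <- square_series(r$stack, r$grid)
  ev <- detect_events_all(ser, r$grid, event_filter_config(fps = 50))
  ep <- detect_shimmer_episodes(activity_fraction(ser), 0.15)
  expect_equal(nrow(ep), 1)
  kept <- filter_events(ev, ep)
  removed <- ev[!(onset_key(ev) %in% onset_key(kept)), ]
  # everything removed overlaps the episode; everything kept does not
  expect_true(all(removed$onset_frame + removed$duration_frames - 1 >=
                    ep$start_frame & removed$onset_frame <= ep$end_frame))
  expect_true(all(kept$onset_frame + kept$duration_frames - 1 <
                    ep$start_frame | kept$onset_frame > ep$end_frame))
})
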