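test_that("the flicker renewal process honours rate and refractory gap", {
  expect_length(simulate_flicker_process(0, 1, 1000, 50, seed = 1), 0)
  expect_error(simulate_flicker_process(-1, 1, 100, 50), "rate")
  expect_error(simulate_flicker_process(0.1, 1, 100, -50), "fps")

  # enforced gap: successive onsets differ by more than min_gap_s * fps
  for (s in 1:10) {
    on <- simulate_flicker_process(0.5, 1, 5000, 50, seed = s)
    if (length(on) > 1) expect_true(min(diff(on)) > 50)
    expect_true(all(on >= 0 & on <= 4998))
  }
})

test_that("the renewal process long-run rate matches its target", {
  # rate 0.1/s with a 1 s gap: mean interarrival 10 s, so ~20 events per
  # 200 s run; check the pooled empirical rate against 0.1 within 3 SE
  counts <- sapply(1:40, function(s)
    length(simulate_flicker_process(0.1, 1, 10000, 50, seed = s)))
  rates <- counts / 200
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.1), 3 * se)
})

test_that("rendering is deterministic and seeds only affect noise", {
  sq <- all_squares(3, 3)
  sc <- scene_config(3, 3, square_px = 4, fps = 50, n_frames = 60,
                     noise_sd = 1,
                     cohorts = list(cohort_spec(sq, 0.5, 10, 2)), seed = 5)
  r1 <- render_frames(sc)
  r2 <- render_frames(sc)
  expect_identical(r1$stack, r2$stack)
  expect_identical(r1$ground_truth, r2$ground_truth)

  # explicit events: ground truth is seed-independent, pixel noise is not
  ev <- data.frame(row = 1, col = 1, onset_frame = 10, duration_frames = 2,
                   amplitude = 20)
  sca <- scene_config(3, 3, square_px = 4, fps = 50, n_frames = 40,
                      noise_sd = 1, events = ev, seed = 1)
  scb <- scene_config(3, 3, square_px = 4, fps = 50, n_frames = 40,
                      noise_sd = 1, events = ev, seed = 2)
  ra <- render_frames(sca); rb <- render_frames(scb)
  expect_false(identical(ra$stack, rb$stack))
  expect_identical(ra$ground_truth$events[, c("row", "col", "onset_frame")],
                   rb$ground_truth$events[, c("row", "col", "onset_frame")])
})

test_that("a rendered event is visible in the difference series exactly at
           its onset and duration", {
  ev <- data.frame(row = 2, col = 2, onset_frame = 10, duration_frames = 2,
                   amplitude = 30)
  sc <- scene_config(5, 5, square_px = 6, fps = 50, n_frames = 20,
                     noise_sd = 0, events = ev)
  r <- render_frames(sc)
  ser <- square_series(r$stack, r$grid)
  tr <- square_trace(ser, r$grid, 2, 2)
  # series index t = transition between frames t and t+1 (0-based);
  # R vector position t+1
  expect_true(all(tr[c(11, 12)] > 2.0))
  expect_true(all(tr[-c(11, 12)] == 0))
  other <- ser[, -(2 * 5 + 2 + 1)]
  expect_true(all(other == 0))
})

test_that("waves flip squares by Chebyshev distance at constant speed", {
  sc <- scene_config(6, 7, square_px = 4, fps = 50, n_frames = 50,
                     waves = list(wave_spec(c(0, 0), start_frame = 5,
                                            speed = 1)), seed = 3)
  gt <- simulate_ground_truth(sc)
  ev <- gt$events
  expect_equal(nrow(ev), 6 * 7)
  # brute-force distance map
  for (i in seq_len(nrow(ev))) {
    d <- max(abs(ev$row[i] - 0), abs(ev$col[i] - 0))
    expect_equal(ev$onset_frame[i], 5 + d)
  }
  expect_equal(gt$trigger_registry$row, 0)
  expect_equal(gt$trigger_registry$col, 0)

  # half speed doubles the arrival lag
  sc2 <- scene_config(6, 7, square_px = 4, fps = 50, n_frames = 50,
                      waves = list(wave_spec(c(0, 0), start_frame = 5,
                                             speed = 0.5)), seed = 3)
  ev2 <- simulate_ground_truth(sc2)$events
  d2 <- pmax(ev2$row, ev2$col)
  expect_equal(ev2$onset_frame, 5 + 2 * d2)
})

test_that("ground-truth event counts equal the realized renewal counts", {
  sq1 <- all_squares(3, 3)[1:4, ]
  sq2 <- all_squares(3, 3)[5:9, ]
  sc <- scene_config(3, 3, fps = 50, n_frames = 2000,
                     cohorts = list(
                       cohort_spec(sq1, 0.4, 8, label = "a"),
                       cohort_spec(sq2, 0.2, 5, label = "b")),
                     seed = 9)
  gt <- simulate_ground_truth(sc)
  expect_equal(sort(unique(gt$events$cohort)), c("a", "b"))
  # per-square counts: every square of an active cohort appears; all events
  # respect the 1 s refractory gap within a square
  by_sq <- split(gt$events, paste(gt$events$row, gt$events$col))
  for (e in by_sq) {
    if (nrow(e) > 1) expect_true(min(diff(sort(e$onset_frame))) > 50)
  }
})

test_that("ground truth round-trips losslessly through CSV", {
  sc <- scene_config(4, 4, fps = 25, n_frames = 300,
                     cohorts = list(cohort_spec(all_squares(4, 4), 0.3, 9, 2)),
                     waves = list(wave_spec(c(1, 1), 20)), seed = 13)
  gt <- simulate_ground_truth(sc)
  stem <- file.path(withr::local_tempdir(), "gt")
  write_ground_truth(gt, stem)
  back <- read_ground_truth(stem)
  expect_equal(back$events, gt$events, tolerance = 1e-12)
  expect_equal(back$trigger_registry, gt$trigger_registry)
})

test_that("sustained mouth-zone motion spans the whole series", {
  mz <- list(squares = data.frame(row = 0, col = 0), amplitude = 10)
  sc <- scene_config(3, 3, square_px = 4, fps = 50, n_frames = 30,
                     mouth_zone = mz, seed = 2)
  r <- render_frames(sc)
  ser <- square_series(r$stack, r$grid)
  tr <- square_trace(ser, r$grid, 0, 0)
  expect_true(all(tr > 2.0))
  # sustained motion must NOT be detected as flickering
  ev <- detect_events_all(ser, r$grid, event_filter_config(fps = 50))
  expect_equal(nrow(ev), 0)
})
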