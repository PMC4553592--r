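#' Cohort specification for the synthetic generator
#'
#' A cohort is a set of squares sharing a flicker regime: a renewal-process
#' event rate, an amplitude distribution (square-level dlum produced per
#' event frame) and a duration distribution over 1-3 frames.
#'
#' @param squares data.frame of 0-based \code{row}, \code{col}.
#' @param flicker_rate events per second per square (>= 0).
#' @param amplitude_mean,amplitude_sd normal amplitude parameters in dlum
#'   units; draws are truncated below at \code{amplitude_min} so active
#'   cohorts stay detectable.
#' @param duration_probs probabilities of 1-, 2- and 3-frame events
#'   (default \code{c(0.5, 0.3, 0.2)}).
#' @param min_gap_s minimal onset-to-onset interval on one square in
#'   seconds (default 1.0, the typical natural repetition interval).
#' @param amplitude_min lower truncation of the amplitude draw (default
#'   2.5, just above the 2.0 detection threshold).
#' @param label cohort label stamped on ground-truth events.
#' @return a \code{cohort_spec} list.
#' @export
cohort_spec <- function(squares, flicker_rate, amplitude_mean,
                        amplitude_sd = 0, duration_probs = c(0.5, 0.3, 0.2),
                        min_gap_s = 1.0, amplitude_min = 2.5,
                        label = "cohort") {
  if (flicker_rate < 0) stop("flicker_rate must be >= 0")
  if (length(duration_probs) != 3 || any(duration_probs < 0)) {
    stop("duration_probs must be 3 non-negative weights for 1-3 frames")
  }
  structure(list(squares = as.data.frame(squares)[, c("row", "col")],
                 flicker_rate = flicker_rate,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 duration_probs = duration_probs / sum(duration_probs),
                 min_gap_s = min_gap_s, amplitude_min = amplitude_min,
                 label = label),
            class = "cohort_spec")
}

#' Shimmering-wave specification for the synthetic generator
#'
#' A wave starts at a trigger square and expands outward at constant speed;
#' a square at Chebyshev distance d from the source flips at
#' \code{start_frame + round(d / speed)}. Each square participates with
#' probability \code{participation_prob} (the trigger square always does).
#'
#' @param trigger_square 0-based \code{c(row, col)} source square.
#' @param start_frame 0-based difference-series index at which the source
#'   flips (>= 0).
#' @param speed propagation speed in squares per frame (> 0).
#' @param participation_prob Bernoulli participation probability.
#' @param flip_amplitude square-level dlum of a wave flip.
#' @param flip_duration frames per flip (default 2).
#' @param max_radius optional maximal Chebyshev radius (default Inf =
#'   whole grid).
#' @return a \code{wave_spec} list.
#' @export
wave_spec <- function(trigger_square, start_frame, speed = 1,
                      participation_prob = 1, flip_amplitude = 20,
                      flip_duration = 2L, max_radius = Inf) {
  if (speed <= 0) stop("speed must be positive")
  if (start_frame < 0) stop("start_frame must be >= 0")
  structure(list(trigger_square = as.integer(trigger_square),
                 start_frame = as.integer(start_frame), speed = speed,
                 participation_prob = participation_prob,
                 flip_amplitude = flip_amplitude,
                 flip_duration = as.integer(flip_duration),
                 max_radius = max_radius),
            class = "wave_spec")
}

#' Scene configuration for the synthetic nest-video generator
#'
#' Defines a synthetic nest scene: the test-square lattice, frame rate and
#' length, background and sensor noise, flicker cohorts, shimmering waves
#' and a sustained-motion mouth zone. Rendering a scene yields an 8-bit
#' frame stack plus the exact ground-truth event log, so detection and the
#' cohort statistics can be validated against known truth.
#'
#' @param grid_rows,grid_cols lattice size in squares (>= 3 each).
#' @param square_px pixels per square side.
#' @param fps frame rate in Hz (field footage used 25 or 50).
#' @param n_frames number of frames.
#' @param background_lum background luminance (8-bit, default 128).
#' @param bee_lum resting luminance of the bee ellipse (default 88).
#' @param noise_sd Gaussian sensor noise sd in luminance units (>= 0).
#' @param mouth_zone optional list with \code{squares} (data.frame row/col)
#'   and \code{amplitude} (dlum per frame) of sustained mouth-zone motion.
#' @param cohorts list of \code{\link{cohort_spec}}.
#' @param waves list of \code{\link{wave_spec}}.
#' @param events optional explicit event data.frame (\code{row}, \code{col},
#'   \code{onset_frame}, \code{duration_frames}, \code{amplitude}) used
#'   verbatim instead of stochastic cohort simulation (cohorts are then
#'   ignored); such ground truth is seed-independent.
#' @param seed integer RNG seed; the whole scene is a pure function of the
#'   config including this seed.
#' @return a \code{scene_config} list.
#' @export
scene_config <- function(grid_rows, grid_cols, square_px = 6L, fps = 50,
                         n_frames = 500L, background_lum = 128,
                         bee_lum = 88, noise_sd = 0, mouth_zone = NULL,
                         cohorts = list(), waves = list(), events = NULL,
                         seed = 1L) {
  if (grid_rows < 3 || grid_cols < 3) stop("grid must be at least 3 x 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (fps <= 0) stop("fps must be positive")
  if (square_px < 2) stop("square_px must be >= 2 (the bee ellipse needs pixels)")
  if (!is.null(mouth_zone)) {
    mz <- mouth_zone$squares
    if (any(mz$row < 0 | mz$row >= grid_rows | mz$col < 0 |
              mz$col >= grid_cols)) {
      stop("mouth_zone squares must lie inside the grid")
    }
    if (is.null(mouth_zone$amplitude)) mouth_zone$amplitude <- 10
  }
  for (w in waves) {
    if (w$trigger_square[1] < 0 || w$trigger_square[1] >= grid_rows ||
        w$trigger_square[2] < 0 || w$trigger_square[2] >= grid_cols) {
      stop("wave trigger square outside grid")
    }
  }
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 square_px = as.integer(square_px), fps = fps,
                 n_frames = as.integer(n_frames),
                 background_lum = background_lum, bee_lum = bee_lum,
                 noise_sd = noise_sd, mouth_zone = mouth_zone,
                 cohorts = cohorts, waves = waves, events = events,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Simulate one square's flicker onset process
#'
#' Renewal process with a refractory period: inter-event times are
#' \code{min_gap_s} plus an exponential excess with mean
#' \code{max(1/rate - min_gap_s, eps)}, so the long-run event rate
#' approaches \code{min(rate, 1/min_gap_s)}. Onsets are returned as
#' 0-based difference-series indices (index t is the transition between
#' frames t and t+1) and successive onsets are guaranteed to differ by
#' strictly more than \code{min_gap_s * fps} frames.
#'
#' @param rate target events per second (>= 0; 0 gives no events).
#' @param min_gap_s refractory interval in seconds (>= 0).
#' @param n_frames length of the scene in frames.
#' @param fps frame rate in Hz (> 0).
#' @param seed optional integer seed; if NULL the current RNG stream is
#'   used.
#' @return sorted integer vector of onset indices in [0, n_frames - 2].
#' @export
simulate_flicker_process <- function(rate, min_gap_s, n_frames, fps,
                                     seed = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  if (fps <= 0) stop("fps must be positive")
  if (min_gap_s < 0) stop("min_gap_s must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(integer())
  horizon_s <- n_frames / fps
  excess_mean <- max(1 / rate - min_gap_s, 1e-9)
  gap_frames <- min_gap_s * fps
  onsets <- integer()
  t <- stats::rexp(1, rate = 1 / excess_mean)  # no refractory before 1st
  last <- -Inf
  while (t < horizon_s) {
    f <- max(0L, as.integer(floor(t * fps)))
    if (f - last <= gap_frames) f <- as.integer(last + floor(gap_frames) + 1L)
    if (f > n_frames - 2L) break
    onsets <- c(onsets, f)
    last <- f
    t <- max(t, f / fps) + min_gap_s + stats::rexp(1, rate = 1 / excess_mean)
  }
  onsets
}

# Draw from a normal truncated below at `lo` (inverse-CDF method).
rnorm_trunc <- function(n, mean, sd, lo) {
  if (sd <= 0) return(rep(max(mean, lo), n))
  plo <- stats::pnorm(lo, mean, sd)
  if (plo >= 1) return(rep(lo, n))
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

# Ground-truth simulation from the current RNG stream (no seeding here;
# render_frames and simulate_ground_truth seed once at entry).
simulate_gt_stream <- function(config) {
  ev <- list()
  if (!is.null(config$events)) {
    e <- as.data.frame(config$events)
    if (is.null(e$kind)) e$kind <- "flicker"
    if (is.null(e$wave_id)) e$wave_id <- NA_integer_
    if (is.null(e$cohort)) e$cohort <- "explicit"
    ev[[length(ev) + 1L]] <- e[, gt_cols()]
  } else {
    for (co in config$cohorts) {
      for (i in seq_len(nrow(co$squares))) {
        onsets <- simulate_flicker_process(co$flicker_rate, co$min_gap_s,
                                           config$n_frames, config$fps)
        # keep events that fit before the end of the series
        n <- length(onsets)
        if (n == 0) next
        dur <- sample.int(3L, n, replace = TRUE, prob = co$duration_probs)
        amp <- rnorm_trunc(n, co$amplitude_mean, co$amplitude_sd,
                           co$amplitude_min)
        keep <- onsets + dur - 1L <= config$n_frames - 2L
        if (!any(keep)) next
        ev[[length(ev) + 1L]] <- data.frame(
          row = co$squares$row[i], col = co$squares$col[i],
          onset_frame = onsets[keep], duration_frames = dur[keep],
          amplitude = amp[keep], kind = "flicker",
          wave_id = NA_integer_, cohort = co$label)
      }
    }
  }
  registry <- data.frame(wave_id = integer(), row = integer(),
                         col = integer(), start_frame = integer())
  for (wi in seq_along(config$waves)) {
    w <- config$waves[[wi]]
    registry <- rbind(registry, data.frame(
      wave_id = wi, row = w$trigger_square[1], col = w$trigger_square[2],
      start_frame = w$start_frame))
    rows <- rep(0:(config$grid_rows - 1L), each = config$grid_cols)
    cols <- rep(0:(config$grid_cols - 1L), times = config$grid_rows)
    d <- pmax(abs(rows - w$trigger_square[1]), abs(cols - w$trigger_square[2]))
    onset <- w$start_frame + as.integer(round(d / w$speed))
    part <- stats::runif(length(d)) < w$participation_prob | d == 0
    keep <- part & d <= w$max_radius &
      onset + w$flip_duration - 1L <= config$n_frames - 2L
    if (any(keep)) {
      ev[[length(ev) + 1L]] <- data.frame(
        row = rows[keep], col = cols[keep], onset_frame = onset[keep],
        duration_frames = w$flip_duration, amplitude = w$flip_amplitude,
        kind = "wave_flip", wave_id = wi, cohort = "wave")
    }
  }
  if (!is.null(config$mouth_zone)) {
    mz <- config$mouth_zone
    ev[[length(ev) + 1L]] <- data.frame(
      row = mz$squares$row, col = mz$squares$col, onset_frame = 0L,
      duration_frames = config$n_frames - 1L, amplitude = rep(mz$amplitude,
        nrow(mz$squares)),
      kind = "sustained", wave_id = NA_integer_, cohort = "mouth_zone")
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    stats::setNames(data.frame(integer(), integer(), integer(), integer(),
                               numeric(), character(), integer(),
                               character()), gt_cols())
  events <- events[order(events$row, events$col, events$onset_frame), ]
  rownames(events) <- NULL
  list(events = events, trigger_registry = registry)
}

gt_cols <- function() c("row", "col", "onset_frame", "duration_frames",
                        "amplitude", "kind", "wave_id", "cohort")

#' Simulate ground truth for a scene without rendering frames
#'
#' Runs only the event-level simulation of \code{\link{render_frames}}:
#' cohort renewal processes, wave flips and sustained mouth-zone motion.
#' Useful for statistical experiments where the pixel stage is not needed.
#'
#' @param config a \code{\link{scene_config}}.
#' @return list with \code{events} (data.frame: row, col, onset_frame,
#'   duration_frames, amplitude, kind, wave_id, cohort) and
#'   \code{trigger_registry} (wave_id, row, col, start_frame).
#' @export
simulate_ground_truth <- function(config) {
  set.seed(config$seed)
  simulate_gt_stream(config)
}

# Ellipse pixel offsets (1-based row/col within a square block) of the
# rendered bee: semi-axes 0.45 and 0.30 of the square side.
ellipse_pixels <- function(square_px) {
  ctr <- (square_px + 1) / 2
  ij <- expand.grid(i = seq_len(square_px), j = seq_len(square_px))
  a <- 0.45 * square_px; b <- 0.30 * square_px
  inside <- ((ij$i - ctr) / b)^2 + ((ij$j - ctr) / a)^2 <= 1
  ij[inside, , drop = FALSE]
}

#' Render a synthetic nest scene to an 8-bit frame stack
#'
#' Draws one bee (a filled ellipse) per test square on a uniform
#' background and translates every ground-truth event into luminance
#' toggles of the ellipse: an event of duration d changes the ellipse
#' luminance at exactly d consecutive frame transitions (alternating
#' between the standing level and a shifted level, the shift sized so the
#' square-mean |frame difference| equals the event amplitude), then the
#' level stands still. Frame differencing therefore recovers each event at
#' its exact onset and duration. Gaussian sensor noise is added per pixel
#' and frame; values are clipped to [0, 255] and rounded.
#'
#' @param config a \code{\link{scene_config}}.
#' @return list with \code{stack} (integer array height x width x
#'   n_frames, attribute \code{fps}; attribute \code{clipped} flags
#'   luminance saturation), \code{ground_truth} (see
#'   \code{\link{simulate_ground_truth}}) and \code{grid} (the matching
#'   \code{\link{build_grid}} result).
#' @export
render_frames <- function(config) {
  set.seed(config$seed)
  gt <- simulate_gt_stream(config)
  s <- config$square_px
  H <- config$grid_rows * s
  W <- config$grid_cols * s
  nsq <- config$grid_rows * config$grid_cols
  ep <- ellipse_pixels(s)
  n_ell <- nrow(ep)
  # linear pixel indices of each square's ellipse in the H x W frame
  sq_rows <- rep(0:(config$grid_rows - 1L), each = config$grid_cols)
  sq_cols <- rep(0:(config$grid_cols - 1L), times = config$grid_rows)
  ell_idx <- lapply(seq_len(nsq), function(k) {
    (sq_cols[k] * s + ep$j - 1L) * H + sq_rows[k] * s + ep$i
  })
  base <- matrix(config$background_lum, H, W)
  for (k in seq_len(nsq)) base[ell_idx[[k]]] <- config$bee_lum
  clipped <- FALSE

  # per-square luminance-offset timeline (frames x squares), from toggles
  offsets <- matrix(0, config$n_frames, nsq)
  if (nrow(gt$events) > 0) {
    evs <- gt$events
    evs$sq <- evs$row * config$grid_cols + evs$col + 1L
    for (sq in unique(evs$sq)) {
      e <- evs[evs$sq == sq, , drop = FALSE]
      e <- e[order(e$onset_frame), , drop = FALSE]
      cur <- 0
      for (i in seq_len(nrow(e))) {
        shift <- e$amplitude[i] * s^2 / n_ell
        hi <- 255 - config$bee_lum - cur   # headroom above the standing level
        down <- config$bee_lum + cur       # headroom below
        # prefer toggling back toward the resting level so repeated events
        # do not ratchet the luminance into saturation
        target <- if (cur >= shift) cur - shift
          else if (shift <= hi) cur + shift
          else if (shift <= down) cur - shift
          else { clipped <- TRUE; cur + max(hi, 0) }
        # onset o in series indexing: first toggled frame is o + 1 (0-based)
        f0 <- e$onset_frame[i] + 1L; d <- e$duration_frames[i]
        kk <- seq_len(d) - 1L
        lev <- ifelse(kk %% 2L == 0L, target, cur)
        offsets[f0 + kk + 1L, sq] <- lev
        stand <- lev[d]
        if (f0 + d <= config$n_frames - 1L) {
          offsets[(f0 + d + 1L):config$n_frames, sq] <- stand
        }
        cur <- stand
      }
    }
  }

  stack <- array(0L, dim = c(H, W, config$n_frames))
  for (t in seq_len(config$n_frames)) {
    fr <- base
    nz <- which(offsets[t, ] != 0)
    for (sq in nz) fr[ell_idx[[sq]]] <- config$bee_lum + offsets[t, sq]
    if (config$noise_sd > 0) {
      fr <- fr + stats::rnorm(H * W, 0, config$noise_sd)
    }
    if (any(fr < 0 | fr > 255)) clipped <- TRUE
    stack[, , t] <- as.integer(round(pmin(pmax(fr, 0), 255)))
  }
  attr(stack, "fps") <- config$fps
  attr(stack, "clipped") <- clipped
  if (clipped) warning("luminance clipped to [0, 255] during rendering")
  grid <- build_grid(c(H, W), s)
  list(stack = stack, ground_truth = gt, grid = grid)
}
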