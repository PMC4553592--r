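#' Event-filter configuration for flicker detection
#'
#' Bundles the interval-filter constants used to separate brief flickering
#' transients from sustained motion. A flickering event is a run of
#' supra-threshold square-level dlum values lasting at most
#' \code{max_duration_frames} frames; longer runs (fanning, walking,
#' dancing) are rejected. Successive events on one square closer than
#' \code{min_gap_s} (onset to onset) are merged, reflecting the typical
#' > 1 s repetition interval of natural flickering.
#'
#' @param detect_threshold square-level dlum cut-off; an event frame must
#'   exceed this strictly (default 2.0).
#' @param max_duration_frames maximal run length counted as a flicker
#'   (default 3, i.e. 60 ms at 50 fps).
#' @param min_gap_s onset-to-onset refractory window in seconds
#'   (default 1.0).
#' @param fps frame rate of the footage in Hz.
#' @return an \code{event_filter_config} list.
#' @export
event_filter_config <- function(detect_threshold = 2.0,
                                max_duration_frames = 3L,
                                min_gap_s = 1.0, fps = 50) {
  if (detect_threshold <= 0) stop("detect_threshold must be positive")
  if (max_duration_frames < 1) stop("max_duration_frames must be >= 1")
  if (fps <= 0) stop("fps must be positive")
  if (min_gap_s < 0) stop("min_gap_s must be non-negative")
  structure(list(detect_threshold = detect_threshold,
                 max_duration_frames = as.integer(max_duration_frames),
                 min_gap_s = min_gap_s, fps = fps),
            class = "event_filter_config")
}

# Maximal supra-threshold runs of a single trace; returns data.frame of
# onset (0-based series index), length, peak and sum of the run.
supra_runs <- function(trace, threshold) {
  supra <- trace > threshold
  if (!any(supra)) {
    return(data.frame(onset = integer(), len = integer(),
                      peak = numeric(), sum = numeric()))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    onset = starts - 1L,
    len = ends - starts + 1L,
    peak = mapply(function(s, e) max(trace[s:e]), starts, ends),
    sum = mapply(function(s, e) sum(trace[s:e]), starts, ends)
  )
}

#' Detect flickering events in one square's dlum trace
#'
#' Scans a square-level motion trace for maximal runs of values strictly
#' above the detection threshold. Runs of 1 to \code{max_duration_frames}
#' frames become flicker events; longer runs are classified as sustained
#' (non-flicker) motion and produce no event. Events whose onsets fall
#' within \code{min_gap_s} of the previous retained onset are merged into
#' the earlier event (its summed dlum absorbs the later run; onset and
#' duration keep the earlier run's values).
#'
#' @param trace numeric vector, one square's dlum per difference frame
#'   (finite, non-negative).
#' @param cfg an \code{\link{event_filter_config}}.
#' @param row,col optional 0-based square coordinates stamped onto the
#'   events (default 0, 0).
#' @return data.frame with columns \code{row}, \code{col},
#'   \code{onset_frame} (0-based index into the difference series),
#'   \code{duration_frames}, \code{peak_dlum}, \code{sum_dlum}.
#' @export
detect_events <- function(trace, cfg, row = 0L, col = 0L) {
  stopifnot(inherits(cfg, "event_filter_config"))
  if (any(!is.finite(trace)) || any(trace < 0)) {
    stop("trace must be finite and non-negative")
  }
  runs <- supra_runs(trace, cfg$detect_threshold)
  runs <- runs[runs$len <= cfg$max_duration_frames, , drop = FALSE]
  ev <- empty_events()
  if (nrow(runs) > 0) {
    gap_frames <- cfg$min_gap_s * cfg$fps
    keep_onset <- -Inf
    rows_out <- list()
    for (i in seq_len(nrow(runs))) {
      if (runs$onset[i] - keep_onset < gap_frames && length(rows_out) > 0) {
        # refractory merge: fold the repeat into the earlier event
        j <- length(rows_out)
        rows_out[[j]]$sum_dlum <- rows_out[[j]]$sum_dlum + runs$sum[i]
        rows_out[[j]]$peak_dlum <- max(rows_out[[j]]$peak_dlum, runs$peak[i])
      } else {
        rows_out[[length(rows_out) + 1L]] <- data.frame(
          row = as.integer(row), col = as.integer(col),
          onset_frame = runs$onset[i], duration_frames = runs$len[i],
          peak_dlum = runs$peak[i], sum_dlum = runs$sum[i])
        keep_onset <- runs$onset[i]
      }
    }
    ev <- do.call(rbind, rows_out)
  }
  rownames(ev) <- NULL
  ev
}

empty_events <- function() {
  data.frame(row = integer(), col = integer(), onset_frame = integer(),
             duration_frames = integer(), peak_dlum = numeric(),
             sum_dlum = numeric())
}

#' Detect flickering events over all squares of a series
#'
#' Applies \code{\link{detect_events}} to every column of a
#' \code{\link{square_series}} matrix.
#'
#' @param series a \code{square_series} matrix ((n_frames-1) x n_squares).
#' @param grid the \code{assessment_grid} that defines the column order.
#' @param cfg an \code{\link{event_filter_config}}.
#' @return data.frame of events, see \code{\link{detect_events}}.
#' @export
detect_events_all <- function(series, grid, cfg) {
  sq <- grid_squares(grid)
  out <- lapply(seq_len(ncol(series)), function(j) {
    detect_events(as.numeric(series[, j]), cfg,
                  row = sq$row[j], col = sq$col[j])
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_events()
  rownames(res) <- NULL
  res
}

#' Fraction of squares simultaneously above threshold, per frame
#'
#' @param series a \code{square_series} matrix.
#' @param threshold dlum cut-off (strict, default 2.0).
#' @return numeric vector in [0, 1], one value per difference frame.
#' @export
activity_fraction <- function(series, threshold = 2.0) {
  rowMeans(series > threshold)
}

#' Detect shimmering-wave episodes from simultaneous square activity
#'
#' Shimmering waves drive many squares above threshold at once and make
#' flicker detection impossible while they last. This marks the frames to
#' mask: maximal runs of frames whose active-square fraction is at least
#' \code{frac_threshold} and that last at least \code{min_len_frames}
#' frames become episodes.
#'
#' @param fraction per-frame active-square fraction in [0, 1] (from
#'   \code{\link{activity_fraction}}).
#' @param frac_threshold minimal simultaneous fraction (default 0.15).
#' @param min_len_frames minimal episode length in frames (default 3).
#' @return data.frame with 0-based inclusive \code{start_frame},
#'   \code{end_frame}; episodes sorted and disjoint.
#' @export
detect_shimmer_episodes <- function(fraction, frac_threshold = 0.15,
                                    min_len_frames = 3L) {
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0, 1]")
  hot <- fraction >= frac_threshold
  out <- data.frame(start_frame = integer(), end_frame = integer())
  if (any(hot)) {
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len_frames
    out <- data.frame(start_frame = starts[keep] - 1L,
                      end_frame = ends[keep] - 1L)
  }
  out
}

#' Apply shimmer-episode and exclusion-zone filters to detected events
#'
#' Removes events that lie in masked (non-active) squares, e.g. the mouth
#' zone, and events any frame of which overlaps a shimmering episode,
#' during which flicker detection is unreliable.
#'
#' @param events event data.frame (see \code{\link{detect_events}}).
#' @param episodes episode data.frame (see
#'   \code{\link{detect_shimmer_episodes}}); may have zero rows.
#' @param active_squares data.frame of 0-based \code{row}, \code{col} of
#'   squares retained for analysis, or NULL to keep all squares.
#' @return the filtered event data.frame (a subset of the input rows).
#' @export
filter_events <- function(events, episodes = NULL, active_squares = NULL) {
  keep <- rep(TRUE, nrow(events))
  if (!is.null(active_squares) && nrow(events) > 0) {
    key <- paste(events$row, events$col)
    keep <- keep & key %in% paste(active_squares$row, active_squares$col)
  }
  if (!is.null(episodes) && nrow(episodes) > 0 && nrow(events) > 0) {
    ev_end <- events$onset_frame + events$duration_frames - 1L
    overlaps <- rep(FALSE, nrow(events))
    for (i in seq_len(nrow(episodes))) {
      overlaps <- overlaps |
        (events$onset_frame <= episodes$end_frame[i] &
           ev_end >= episodes$start_frame[i])
    }
    keep <- keep & !overlaps
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
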