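#' Assign a trigger-site neighborhood to a wave source square
#'
#' A shimmering wave's trigger site is the manually (or synthetically)
#' registered source square plus the eight squares encircling it: each of
#' the (up to) nine squares receives trigger-activity value 1.0.
#' Neighbors falling outside the grid are clipped, so a corner source
#' yields 4 squares and an edge source 6.
#'
#' @param source 0-based \code{c(row, col)} of the source square.
#' @param grid an \code{assessment_grid}.
#' @return data.frame with \code{row}, \code{col}, \code{value} (all 1.0).
#' @export
assign_trigger_site <- function(source, grid) {
  r <- as.integer(source[1]); c <- as.integer(source[2])
  if (r < 0 || r >= grid$rows || c < 0 || c >= grid$cols) {
    stop("source square outside grid")
  }
  rr <- rep((r - 1L):(r + 1L), each = 3L)
  cc <- rep((c - 1L):(c + 1L), times = 3L)
  keep <- rr >= 0 & rr < grid$rows & cc >= 0 & cc < grid$cols
  data.frame(row = rr[keep], col = cc[keep], value = 1.0)
}

#' Pool trigger activity over a wave registry
#'
#' Accumulates the 3 x 3 trigger-site assignments of every registered wave
#' source into a per-square trigger-activity map for one experimental
#' phase (or for all phases pooled).
#'
#' @param registry data.frame with columns \code{wave_id}, \code{phase},
#'   \code{row}, \code{col} (0-based source squares).
#' @param grid an \code{assessment_grid}.
#' @param phase_label phase to select, or NULL to pool all rows.
#' @return a \code{trigger_site_map}: list with \code{activity}
#'   (rows x cols matrix), \code{phase_label}, \code{n_entries}.
#' @export
pool_trigger_activity <- function(registry, grid, phase_label = NULL) {
  if (!is.null(phase_label)) {
    registry <- registry[registry$phase == phase_label, , drop = FALSE]
  }
  activity <- matrix(0, grid$rows, grid$cols)
  for (i in seq_len(nrow(registry))) {
    a <- assign_trigger_site(c(registry$row[i], registry$col[i]), grid)
    activity[cbind(a$row + 1L, a$col + 1L)] <-
      activity[cbind(a$row + 1L, a$col + 1L)] + a$value
  }
  structure(list(activity = activity,
                 phase_label = if (is.null(phase_label)) NA_character_
                               else phase_label,
                 n_entries = nrow(registry)),
            class = "trigger_site_map")
}

#' Scale a trigger-activity map to its phase maximum
#'
#' Divides each square's pooled trigger activity by the maximal value
#' observed in the map, giving the 0-1 (white-to-red when rendered 0-255)
#' scale used for per-phase trigger maps. Scaling is order-preserving; an
#' all-zero map stays all-zero.
#'
#' @param map a \code{trigger_site_map}.
#' @return the map with an added \code{scaled} matrix (values in [0, 1]).
#' @export
scale_map <- function(map) {
  m <- max(map$activity)
  map$scaled <- if (m > 0) map$activity / m else map$activity
  map
}

#' Partition active squares into trigger and non-trigger cohorts
#'
#' Trigger sites (ts) are the active squares with pooled trigger activity
#' > 0 in the phase under analysis; every other active square is a
#' non-trigger site (nts).
#'
#' @param map a \code{trigger_site_map} (scaled or not; the partition is
#'   scale-invariant).
#' @param active_squares data.frame of 0-based \code{row}, \code{col}
#'   (from \code{\link{apply_mask}}).
#' @return a \code{cohort_partition}: list of data.frames \code{ts} and
#'   \code{nts} (columns \code{row}, \code{col}).
#' @export
partition_cohorts <- function(map, active_squares) {
  act <- map$activity[cbind(active_squares$row + 1L,
                            active_squares$col + 1L)]
  structure(list(ts = active_squares[act > 0, , drop = FALSE],
                 nts = active_squares[act == 0, , drop = FALSE],
                 phase_label = map$phase_label),
            class = "cohort_partition")
}

#' Construct a ts/nts cohort partition directly
#'
#' Mostly used with synthetic scenes where the trigger cohort is designed
#' rather than pooled from a wave registry.
#'
#' @param ts,nts data.frames of 0-based \code{row}, \code{col}; must be
#'   disjoint.
#' @param phase_label optional phase name.
#' @return a \code{cohort_partition}.
#' @export
cohort_partition <- function(ts, nts, phase_label = NA_character_) {
  ts <- as.data.frame(ts)[, c("row", "col")]
  nts <- as.data.frame(nts)[, c("row", "col")]
  if (length(intersect(paste(ts$row, ts$col), paste(nts$row, nts$col)))) {
    stop("ts and nts must be disjoint")
  }
  structure(list(ts = ts, nts = nts, phase_label = phase_label),
            class = "cohort_partition")
}

#' Cohort membership of squares, as a label vector
#'
#' @param partition a \code{cohort_partition}.
#' @param squares data.frame of 0-based \code{row}, \code{col}.
#' @return character vector \code{"ts"}/\code{"nts"}/\code{NA} (NA for
#'   squares outside the partition, i.e. masked squares).
#' @export
cohort_of <- function(partition, squares) {
  key <- paste(squares$row, squares$col)
  out <- rep(NA_character_, nrow(squares))
  out[key %in% paste(partition$ts$row, partition$ts$col)] <- "ts"
  out[key %in% paste(partition$nts$row, partition$nts$col)] <- "nts"
  out
}

#' Render a scaled trigger or activity map as a white-to-red heatmap PNG
#'
#' @param scaled matrix of values in [0, 1].
#' @param path output PNG path.
#' @param px_per_cell magnification factor (default 4).
#' @return the path, invisibly.
#' @export
write_heatmap_png <- function(scaled, path, px_per_cell = 4L) {
  v <- pmin(pmax(scaled, 0), 1)
  big <- v[rep(seq_len(nrow(v)), each = px_per_cell),
           rep(seq_len(ncol(v)), each = px_per_cell), drop = FALSE]
  img <- array(1, dim = c(nrow(big), ncol(big), 3))
  img[, , 2] <- 1 - big
  img[, , 3] <- 1 - big
  png::writePNG(img, target = path)
  invisible(path)
}
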