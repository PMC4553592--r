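#' Write a frame stack as numbered 8-bit grayscale PNG files
#'
#' @param stack integer array height x width x n_frames, values 0-255.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default "frame").
#' @return character vector of written paths, invisibly.
#' @export
write_frames_png <- function(stack, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(stack)[3]
  fmt <- paste0(prefix, "_%0", nchar(as.character(nf)), "d.png")
  paths <- file.path(dir, sprintf(fmt, seq_len(nf) - 1L))
  for (t in seq_len(nf)) {
    png::writePNG(stack[, , t] / 255, target = paths[t])
  }
  invisible(paths)
}

#' Read a frame stack from PNGs in a directory or a multi-page TIFF
#'
#' PNG frames are read in lexicographic file order; RGB images are
#' converted to 8-bit luma. Returns values on the 0-255 scale.
#'
#' @param path a directory of PNG frames or a single .tif/.tiff file.
#' @param fps optional frame rate stored as an attribute.
#' @return numeric array height x width x n_frames.
#' @export
read_frame_stack <- function(path, fps = NULL) {
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found in ", path)
    lapply(files, function(f) as_luma(png::readPNG(f) * 255))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(p) as_luma(p * 255))
  } else {
    stop("path must be a directory of PNGs or a TIFF file")
  }
  d <- dim(frames[[1]])
  stack <- array(0, dim = c(d[1], d[2], length(frames)))
  for (t in seq_along(frames)) stack[, , t] <- frames[[t]]
  if (!is.null(fps)) attr(stack, "fps") <- fps
  stack
}

#' Write / read a ground-truth event log as CSV
#'
#' Round-trips the generator's ground truth (events and trigger registry)
#' losslessly through two CSV files: \code{<stem>_events.csv} and
#' \code{<stem>_registry.csv}.
#'
#' @param gt list with \code{events} and \code{trigger_registry} (see
#'   \code{\link{simulate_ground_truth}}).
#' @param stem path stem without extension.
#' @return \code{write_ground_truth}: the two paths, invisibly;
#'   \code{read_ground_truth}: the ground-truth list.
#' @export
write_ground_truth <- function(gt, stem) {
  ev_path <- paste0(stem, "_events.csv")
  reg_path <- paste0(stem, "_registry.csv")
  utils::write.csv(gt$events, ev_path, row.names = FALSE)
  utils::write.csv(gt$trigger_registry, reg_path, row.names = FALSE)
  invisible(c(ev_path, reg_path))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(stem) {
  events <- utils::read.csv(paste0(stem, "_events.csv"),
                            stringsAsFactors = FALSE)
  registry <- utils::read.csv(paste0(stem, "_registry.csv"),
                              stringsAsFactors = FALSE)
  list(events = events, trigger_registry = registry)
}

#' Write / read a wave trigger registry as CSV
#'
#' Columns: \code{wave_id}, \code{phase}, \code{row}, \code{col} (0-based
#' source squares).
#'
#' @param registry the registry data.frame.
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_trigger_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trigger_registry
#' @export
read_trigger_registry <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an event table as CSV
#'
#' @param events event data.frame (see \code{\link{detect_events}}).
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a square-series dlum matrix as CSV
#'
#' Rows are difference frames, columns squares in row-major 0-based order
#' ("r<row>_c<col>").
#'
#' @param series a \code{square_series} matrix.
#' @param grid the matching \code{assessment_grid}.
#' @param path CSV path.
#' @return the path (write) or a plain matrix (read).
#' @export
write_square_series <- function(series, grid, path) {
  sq <- grid_squares(grid)
  m <- as.data.frame(unclass(series))
  names(m) <- sprintf("r%d_c%d", sq$row, sq$col)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_square_series
#' @export
read_square_series <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Read / write a run configuration as YAML
#'
#' See \code{\link{run_pipeline}} for the recognised keys.
#'
#' @param config a run-config list.
#' @param path YAML path.
#' @return the path (write) or the config list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
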