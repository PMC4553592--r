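#' Pixel-wise absolute luminance difference of two frames
#'
#' Motion between two consecutive video frames is measured as the unsigned
#' per-pixel luminance change (dlum): 0 is motionlessness, 255 the maximum
#' attainable motion intensity on 8-bit footage.
#'
#' @param f1,f2 numeric matrices of equal shape, 8-bit grayscale values
#'   (0-255), or RGB arrays (height x width x 3), which are converted to
#'   luma first.
#' @return a \code{difference_image}: numeric matrix of absolute
#'   differences with attribute \code{frame_index} (index of the later
#'   frame, \code{NA} unless supplied via \code{attr(f2, "frame_index")}).
#' @export
frame_difference <- function(f1, f2) {
  f1 <- as_luma(f1)
  f2 <- as_luma(f2)
  if (!identical(dim(f1), dim(f2))) stop("frames differ in shape")
  d <- abs(f2 - f1)
  attr(d, "frame_index") <- attr(f2, "frame_index", exact = TRUE)
  class(d) <- c("difference_image", class(d))
  d
}

#' Convert an RGB frame to 8-bit luma
#'
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); grayscale matrices pass
#' through unchanged.
#'
#' @param frame matrix (grayscale) or height x width x 3 array (RGB), 0-255.
#' @return numeric grayscale matrix.
#' @export
as_luma <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3 && dim(frame)[3] >= 3) {
    return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  }
  stop("frame must be a grayscale matrix or an RGB array")
}

#' Segment a difference image into a motion mask with strength classes
#'
#' Thresholds the unsigned difference image into a binary motion mask
#' (black-and-white segmentation) and grades masked pixels into weak,
#' medium and strong motion, the three pseudocolour bands used when
#' rendering difference images.
#'
#' @param diff a \code{difference_image} (or plain non-negative matrix).
#' @param seg_threshold segmentation cut-off in luminance units (> 0);
#'   pixels with difference >= threshold are masked, so a cut-off above 255
#'   masks nothing. Default 2.0.
#' @param strength_bounds ascending pair of luminance values separating
#'   weak/medium and medium/strong pixels. Default \code{c(10, 40)}.
#' @return a \code{motion_mask}: list with logical matrix \code{mask} and
#'   integer matrix \code{strength} (0 unmasked, 1 weak, 2 medium, 3
#'   strong).
#' @export
segment_motion <- function(diff, seg_threshold = 2.0,
                           strength_bounds = c(10, 40)) {
  if (seg_threshold <= 0) stop("seg_threshold must be positive")
  if (length(strength_bounds) != 2 ||
      strength_bounds[1] >= strength_bounds[2]) {
    stop("strength_bounds must be two ascending values")
  }
  mask <- diff >= seg_threshold
  strength <- matrix(0L, nrow(diff), ncol(diff))
  strength[mask] <- 1L
  strength[mask & diff >= strength_bounds[1]] <- 2L
  strength[mask & diff >= strength_bounds[2]] <- 3L
  structure(list(mask = mask, strength = strength,
                 seg_threshold = seg_threshold,
                 strength_bounds = strength_bounds),
            class = "motion_mask")
}

# Row/column aggregation operators for fast per-square pooling:
# rowsum-style 0/1 matrices mapping pixels to grid squares.
square_pool_operators <- function(grid) {
  s <- grid$square_px
  ridx <- rep(seq_len(grid$rows), each = s)
  cidx <- rep(seq_len(grid$cols), each = s)
  A <- matrix(0, grid$rows, grid$rows * s)
  A[cbind(ridx, seq_along(ridx))] <- 1
  B <- matrix(0, grid$cols * s, grid$cols)
  B[cbind(seq_along(cidx), cidx)] <- 1
  list(A = A, B = B)
}

#' Pool a difference image into per-square dlum values
#'
#' Aggregates the per-pixel unsigned luminance differences into one motion
#' value per test square. The default reducer is the mean over the square's
#' pixels, which keeps the square-level dlum on the same 0-255 scale as the
#' pixel values regardless of resolution; \code{sum} is offered for
#' area-weighted analyses.
#'
#' @param diff a \code{difference_image}.
#' @param grid an \code{assessment_grid} covering the image.
#' @param reducer \code{"mean"} (default) or \code{"sum"}.
#' @return numeric matrix of shape rows x cols (0-based square (r, c) at
#'   matrix position \code{[r+1, c+1]}).
#' @export
square_luminance <- function(diff, grid, reducer = c("mean", "sum")) {
  reducer <- match.arg(reducer)
  need <- c(grid$origin[2] + grid$rows * grid$square_px,
            grid$origin[1] + grid$cols * grid$square_px)
  if (nrow(diff) < need[1] || ncol(diff) < need[2]) {
    stop("grid extends beyond the image")
  }
  sub <- diff[(grid$origin[2] + 1):need[1],
              (grid$origin[1] + 1):need[2], drop = FALSE]
  op <- square_pool_operators(grid)
  pooled <- op$A %*% sub %*% op$B
  if (reducer == "mean") pooled <- pooled / grid$square_px^2
  unclass(pooled)
}

#' Per-square dlum time series of a frame stack
#'
#' Runs consecutive-frame differencing over a stack and pools each
#' difference image onto the grid, yielding the square-level motion series
#' all event detection operates on. Frame t of the output corresponds to
#' the difference between frames t and t+1 of the stack (so the series has
#' \code{n_frames - 1} time points) and is indexed by the later frame, the
#' frame at which the movement becomes visible.
#'
#' @param stack numeric array height x width x n_frames, 8-bit values.
#' @param grid an \code{assessment_grid}.
#' @param reducer see \code{\link{square_luminance}}.
#' @return a \code{square_series}: numeric matrix (n_frames - 1) x
#'   (rows*cols); column order is row-major over squares, i.e. square
#'   (r, c) is column \code{r*cols + c + 1}. Row t holds the motion at
#'   frame index t (0-based later frame of the pair).
#' @export
square_series <- function(stack, grid, reducer = "mean") {
  nf <- dim(stack)[3]
  if (is.na(nf) || nf < 2) stop("stack must hold at least two frames")
  op <- square_pool_operators(grid)
  rpx <- (grid$origin[2] + 1):(grid$origin[2] + grid$rows * grid$square_px)
  cpx <- (grid$origin[1] + 1):(grid$origin[1] + grid$cols * grid$square_px)
  if (max(rpx) > dim(stack)[1] || max(cpx) > dim(stack)[2]) {
    stop("grid extends beyond the image")
  }
  out <- matrix(0, nf - 1L, grid$rows * grid$cols)
  prev <- stack[rpx, cpx, 1]
  scale <- if (reducer == "mean") grid$square_px^2 else 1
  for (t in 2:nf) {
    cur <- stack[rpx, cpx, t]
    pooled <- op$A %*% abs(cur - prev) %*% op$B / scale
    # row-major square order: transpose of the rows x cols pooled matrix
    out[t - 1L, ] <- as.vector(t(pooled))
    prev <- cur
  }
  structure(out, class = c("square_series", "matrix"),
            fps = attr(stack, "fps", exact = TRUE))
}

#' Extract one square's dlum trace from a square series
#'
#' @param series a \code{square_series} matrix.
#' @param grid the \code{assessment_grid} the series was pooled on.
#' @param row,col 0-based square coordinates.
#' @return numeric vector of length n_frames - 1.
#' @export
square_trace <- function(series, grid, row, col) {
  as.numeric(series[, square_index(grid, row, col)])
}
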