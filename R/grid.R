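#' Build a bee-sized assessment grid over an image
#'
#' Superimposes a lattice of square test cells (one cell approximately the
#' image area occupied by a single surface bee, 15 mm in the field setup)
#' over a pixel image. Squares are indexed 0-based as (row, col), row 0 at
#' the image top, and each square owns the half-open pixel ranges
#' \code{[k*square_px, (k+1)*square_px)} in both directions. Pixels beyond
#' the last full square are not gridded.
#'
#' @param image_shape integer vector \code{c(height, width)} in pixels.
#' @param square_px side length of one test square, in pixels (>= 1).
#' @param origin pixel offset \code{c(x, y)} of square (0, 0); default
#'   \code{c(0, 0)}.
#' @param unit_len_cm physical side length of one square in cm, recorded for
#'   reporting only (default 1.5).
#' @return An object of class \code{assessment_grid} with fields
#'   \code{rows}, \code{cols}, \code{square_px}, \code{origin},
#'   \code{unit_len_cm}, \code{image_shape}.
#' @export
build_grid <- function(image_shape, square_px, origin = c(0, 0),
                       unit_len_cm = 1.5) {
  stopifnot(length(image_shape) == 2, length(origin) == 2)
  square_px <- as.integer(square_px)
  if (square_px < 1L) stop("square_px must be >= 1")
  if (unit_len_cm <= 0) stop("unit_len_cm must be positive")
  height <- as.integer(image_shape[1])
  width <- as.integer(image_shape[2])
  rows <- (height - as.integer(origin[2])) %/% square_px
  cols <- (width - as.integer(origin[1])) %/% square_px
  if (rows < 1L || cols < 1L) {
    stop("square_px larger than the gridded image region")
  }
  structure(
    list(rows = rows, cols = cols, square_px = square_px,
         origin = as.integer(origin), unit_len_cm = unit_len_cm,
         image_shape = c(height, width)),
    class = "assessment_grid"
  )
}

#' @export
print.assessment_grid <- function(x, ...) {
  cat(sprintf(
    "assessment_grid: %d rows x %d cols (%d px squares, %.1f cm unit, %.0f x %.0f cm)\n",
    x$rows, x$cols, x$square_px,
    x$unit_len_cm, x$cols * x$unit_len_cm, x$rows * x$unit_len_cm))
  invisible(x)
}

#' Physical extent of a grid in centimetres
#'
#' @param grid an \code{assessment_grid}.
#' @return numeric \code{c(width_cm, height_cm)}.
#' @export
grid_extent_cm <- function(grid) {
  c(width_cm = grid$cols * grid$unit_len_cm,
    height_cm = grid$rows * grid$unit_len_cm)
}

#' Map a pixel position to its test square
#'
#' Half-open convention: pixel x belongs to column \code{floor((x-ox)/s)},
#' so the boundary pixel \code{x = k*s} starts square k.
#'
#' @param grid an \code{assessment_grid}.
#' @param x,y pixel coordinates (0-based, x rightwards, y downwards);
#'   vectors of equal length are accepted.
#' @return data.frame with 0-based columns \code{row}, \code{col}.
#' @export
map_point_to_square <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  relx <- x - grid$origin[1]
  rely <- y - grid$origin[2]
  col <- floor(relx / grid$square_px)
  row <- floor(rely / grid$square_px)
  bad <- relx < 0 | rely < 0 | col >= grid$cols | row >= grid$rows
  if (any(bad)) {
    stop(sprintf("point outside gridded region (first offender: x=%s, y=%s)",
                 x[which(bad)[1]], y[which(bad)[1]]))
  }
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' All squares of a grid as a data.frame
#'
#' @param grid an \code{assessment_grid}.
#' @return data.frame of 0-based \code{row}, \code{col}, row-major order.
#' @export
grid_squares <- function(grid) {
  data.frame(
    row = rep(seq_len(grid$rows) - 1L, each = grid$cols),
    col = rep(seq_len(grid$cols) - 1L, times = grid$rows)
  )
}

#' Linear 1-based index of (row, col) squares, row-major
#' @keywords internal
square_index <- function(grid, row, col) {
  as.integer(row) * grid$cols + as.integer(col) + 1L
}

#' Create an exclusion mask over grid squares
#'
#' @param squares data.frame with 0-based \code{row}, \code{col} of squares
#'   to exclude.
#' @param label one of \code{"mouth_zone"}, \code{"off_nest"},
#'   \code{"other"}.
#' @return object of class \code{region_mask}.
#' @export
region_mask <- function(squares, label = c("mouth_zone", "off_nest", "other")) {
  label <- match.arg(label)
  squares <- unique(as.data.frame(squares)[, c("row", "col")])
  structure(list(squares = squares, label = label), class = "region_mask")
}

#' Rasterize a pixel-space polygon to a square mask
#'
#' A square is excluded when its centre lies inside the polygon (even-odd
#' rule, vertices in pixel coordinates). Used for hand-drawn mouth-zone or
#' nest-contour outlines.
#'
#' @param grid an \code{assessment_grid}.
#' @param poly_x,poly_y polygon vertex coordinates in pixels.
#' @param label mask label, see \code{\link{region_mask}}.
#' @return a \code{region_mask}.
#' @export
polygon_mask <- function(grid, poly_x, poly_y, label = "mouth_zone") {
  stopifnot(length(poly_x) == length(poly_y), length(poly_x) >= 3)
  sq <- grid_squares(grid)
  cx <- grid$origin[1] + (sq$col + 0.5) * grid$square_px
  cy <- grid$origin[2] + (sq$row + 0.5) * grid$square_px
  inside <- point_in_polygon(cx, cy, poly_x, poly_y)
  region_mask(sq[inside, , drop = FALSE], label = label)
}

# Even-odd ray-casting point-in-polygon; points exactly on an edge may fall
# on either side, which is immaterial for square centres against hand-drawn
# outlines.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Active squares after applying exclusion masks
#'
#' @param grid an \code{assessment_grid}.
#' @param masks a single \code{region_mask} or a list of them (may be empty).
#' @return data.frame of 0-based \code{row}, \code{col} of active squares.
#' @export
apply_mask <- function(grid, masks = list()) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  all_sq <- grid_squares(grid)
  if (length(masks) == 0) return(all_sq)
  excluded <- do.call(rbind, lapply(masks, function(m) {
    bad <- m$squares$row < 0 | m$squares$row >= grid$rows |
      m$squares$col < 0 | m$squares$col >= grid$cols
    if (any(bad)) stop("mask square outside grid")
    m$squares
  }))
  keep <- !(square_index(grid, all_sq$row, all_sq$col) %in%
              square_index(grid, excluded$row, excluded$col))
  all_sq[keep, , drop = FALSE]
}
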