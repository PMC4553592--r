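# Independent brute-force reference implementations used to cross-check the
# vectorized pipeline code. These deliberately use naive loops.

# per-square mean |difference| series by looping over pixels
naive_square_series <- function(stack, rows, cols, square_px) {
  nf <- dim(stack)[3]
  out <- matrix(0, nf - 1, rows * cols)
  for (t in 2:nf) {
    d <- abs(stack[, , t] - stack[, , t - 1])
    for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
      px <- d[(r * square_px + 1):((r + 1) * square_px),
              (c * square_px + 1):((c + 1) * square_px)]
      out[t - 1, r * cols + c + 1] <- mean(px)
    }
  }
  out
}

# run-length event scan by explicit walking, no merging
naive_runs <- function(trace, threshold, max_dur) {
  events <- list()
  i <- 1
  while (i <= length(trace)) {
    if (trace[i] > threshold) {
      j <- i
      while (j < length(trace) && trace[j + 1] > threshold) j <- j + 1
      if (j - i + 1 <= max_dur) {
        events[[length(events) + 1]] <-
          c(onset = i - 1, len = j - i + 1, sum = sum(trace[i:j]))
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(events) == 0) {
    return(data.frame(onset = numeric(), len = numeric(), sum = numeric()))
  }
  as.data.frame(do.call(rbind, events))
}

# Spearman rho via explicit mid-rank formula (Pearson on ranks)
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# point-to-square by exhaustive rectangle search
naive_point_square <- function(x, y, rows, cols, square_px) {
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    if (x >= c * square_px && x < (c + 1) * square_px &&
        y >= r * square_px && y < (r + 1) * square_px) {
      return(c(r, c))
    }
  }
  stop("point not in any square")
}

# trigger pooling by per-wave scan over all squares
naive_pool <- function(registry, rows, cols) {
  act <- matrix(0, rows, cols)
  for (i in seq_len(nrow(registry))) {
    for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
      if (abs(r - registry$row[i]) <= 1 && abs(c - registry$col[i]) <= 1) {
        act[r + 1, c + 1] <- act[r + 1, c + 1] + 1
      }
    }
  }
  act
}

# small all-squares data.frame
all_squares <- function(rows, cols) {
  expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))[, c("row", "col")]
}

# event key helpers for recall/precision bookkeeping
event_key <- function(d) paste(d$row, d$col, d$onset_frame, d$duration_frames)
onset_key <- function(d) paste(d$row, d$col, d$onset_frame)
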