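#' Per-square flickering rate
#'
#' Number of flicker events per second of observed footage. Rates are kept
#' in Hz throughout; use \code{rate_per_min} for display.
#'
#' @param n_events event count on the square (or an event data.frame, whose
#'   rows are counted).
#' @param observed_s observed duration in seconds (> 0).
#' @return rate in Hz.
#' @export
square_rate <- function(n_events, observed_s) {
  if (observed_s <= 0) stop("observed_s must be positive")
  if (is.data.frame(n_events)) n_events <- nrow(n_events)
  n_events / observed_s
}

#' @rdname square_rate
#' @export
rate_per_min <- function(n_events, observed_s) {
  60 * square_rate(n_events, observed_s)
}

#' Per-square flickering intensity fI
#'
#' fI = sum of event dlum over the reference interval, i.e.
#' \code{sum(sum_dlum) / t_ref}, in dlum units per second. Zero events give
#' fI = 0.
#'
#' @param sum_dlum vector of per-event summed dlum values (or an event
#'   data.frame with a \code{sum_dlum} column).
#' @param t_ref reference interval in seconds (> 0).
#' @return intensity fI.
#' @export
square_intensity <- function(sum_dlum, t_ref) {
  if (t_ref <= 0) stop("t_ref must be positive")
  if (is.data.frame(sum_dlum)) sum_dlum <- sum_dlum$sum_dlum
  sum(sum_dlum) / t_ref
}

#' Per-square rate/intensity records for one phase
#'
#' Tabulates every active square's flickering rate (Hz) and intensity fI
#' over a phase, labelled with its ts/nts cohort.
#'
#' @param events filtered event data.frame for the phase.
#' @param partition a \code{cohort_partition}.
#' @param t_ref analysed phase duration in seconds.
#' @param phase_label phase name stamped on the records.
#' @param all_active if TRUE (default) emit a record for every active
#'   square including zero-rate ones; if FALSE only flickering-active
#'   squares.
#' @return data.frame with \code{row}, \code{col}, \code{cohort},
#'   \code{n_events}, \code{rate_hz}, \code{fI}, \code{phase}.
#' @export
rate_intensity_records <- function(events, partition, t_ref,
                                   phase_label = NA_character_,
                                   all_active = TRUE) {
  active <- rbind(partition$ts, partition$nts)
  key <- paste(active$row, active$col)
  n <- integer(length(key)); s <- numeric(length(key))
  if (nrow(events) > 0) {
    ek <- paste(events$row, events$col)
    agg_n <- tapply(rep(1L, nrow(events)), ek, sum)
    agg_s <- tapply(events$sum_dlum, ek, sum)
    m <- match(names(agg_n), key)
    ok <- !is.na(m)
    n[m[ok]] <- agg_n[ok]
    s[m[ok]] <- agg_s[ok]
  }
  rec <- data.frame(
    row = active$row, col = active$col,
    cohort = cohort_of(partition, active),
    n_events = n,
    rate_hz = n / t_ref,
    fI = s / t_ref,
    phase = phase_label
  )
  if (!all_active) rec <- rec[rec$n_events > 0, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Relative number of flickering-active squares (relF)
#'
#' relF is the fraction of nest test squares showing at least one flicker
#' event in a phase, reported overall (ts+nts) and split by cohort; the
#' denominator is the number of squares covering the nest area, so
#' relF_ts + relF_nts = relF_ts+nts exactly.
#'
#' @param flicker_squares data.frame of 0-based \code{row}, \code{col} of
#'   squares with >= 1 event.
#' @param partition a \code{cohort_partition}.
#' @param nest_squares total number of nest test squares (the 100%
#'   denominator; > 0).
#' @return list with \code{relF_total}, \code{relF_ts}, \code{relF_nts}
#'   (fractions in [0, 1]).
#' @export
relf_metrics <- function(flicker_squares, partition, nest_squares) {
  if (nest_squares <= 0) stop("nest_squares must be positive")
  flicker_squares <- unique(flicker_squares[, c("row", "col")])
  coh <- cohort_of(partition, flicker_squares)
  n_ts <- sum(coh == "ts", na.rm = TRUE)
  n_nts <- sum(coh == "nts", na.rm = TRUE)
  list(relF_total = (n_ts + n_nts) / nest_squares,
       relF_ts = n_ts / nest_squares,
       relF_nts = n_nts / nest_squares)
}

#' Compile rate classes with per-cohort intensity means
#'
#' Sorts per-square records into 30 contiguous half-open rate classes of
#' width 0.03 Hz (class k covers [k*0.03, (k+1)*0.03)); rates at or above
#' the top bound are capped into the last class with a warning. For each
#' class and cohort the mean fI, its SEM (sd/sqrt(n); 0 when n = 1) and n
#' are reported.
#'
#' @param records data.frame from \code{\link{rate_intensity_records}}.
#' @param width class width in Hz (default 0.03).
#' @param n_classes number of classes (default 30).
#' @param drop_zero_rate if TRUE (default) squares with zero events are not
#'   binned (only flickering-active squares enter the compilation).
#' @return data.frame with \code{class_index} (0-based), \code{rate_lo},
#'   \code{rate_hi}, \code{rate_mid}, \code{cohort}, \code{n},
#'   \code{mean_fI}, \code{sem_fI}; empty classes are omitted.
#' @export
bin_rate_classes <- function(records, width = 0.03, n_classes = 30L,
                             drop_zero_rate = TRUE) {
  if (width <= 0) stop("width must be positive")
  if (drop_zero_rate) records <- records[records$rate_hz > 0, , drop = FALSE]
  cls <- floor(records$rate_hz / width)
  capped <- cls >= n_classes
  if (any(capped)) {
    warning(sprintf("%d record(s) above the top rate class; capped", sum(capped)))
    cls[capped] <- n_classes - 1L
  }
  out <- list()
  for (co in unique(records$cohort)) {
    sel <- records$cohort == co
    for (k in sort(unique(cls[sel]))) {
      y <- records$fI[sel & cls == k]
      out[[length(out) + 1L]] <- data.frame(
        class_index = k,
        rate_lo = k * width, rate_hi = (k + 1) * width,
        rate_mid = (k + 0.5) * width,
        cohort = co, n = length(y), mean_fI = mean(y),
        sem_fI = if (length(y) > 1) stats::sd(y) / sqrt(length(y)) else 0)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(class_index = integer(), rate_lo = numeric(),
               rate_hi = numeric(), rate_mid = numeric(),
               cohort = character(), n = integer(), mean_fI = numeric(),
               sem_fI = numeric())
  res <- res[order(res$cohort, res$class_index), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "width") <- width
  attr(res, "n_classes") <- n_classes
  res
}

#' Fit y = a * exp(b * x) by log-linear least squares
#'
#' The rate-intensity curves are summarised by an exponential law fitted as
#' an ordinary least-squares regression of ln(y) on x; a = exp(intercept),
#' b = slope, and R-squared is that of the log-linear regression. Points
#' with y <= 0 cannot enter the log fit and are dropped with a warning.
#'
#' @param x,y numeric vectors (class midpoints and mean intensities).
#' @return list with \code{a}, \code{b}, \code{r_squared}, \code{n_used}.
#' @export
fit_exponential <- function(x, y) {
  stopifnot(length(x) == length(y))
  bad <- !(y > 0) | !is.finite(y) | !is.finite(x)
  if (any(bad)) {
    warning(sprintf("%d point(s) with non-positive y dropped from exponential fit",
                    sum(bad)))
    x <- x[!bad]; y <- y[!bad]
  }
  if (length(x) < 2) stop("need >= 2 points with positive y")
  fit <- stats::lm(log(y) ~ x)
  ly <- log(y)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(a = unname(exp(stats::coef(fit)[1])),
       b = unname(stats::coef(fit)[2]),
       r_squared = r2, n_used = length(x))
}

#' Spearman rank correlation between flickering rate and intensity
#'
#' @param rate,intensity paired numeric vectors (>= 3 pairs); mid-ranks for
#'   ties, two-sided P.
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_rate_intensity <- function(rate, intensity) {
  stopifnot(length(rate) == length(intensity))
  if (length(rate) < 3) stop("need >= 3 pairs")
  if (stats::sd(rate) == 0 || stats::sd(intensity) == 0) {
    warning("constant input; rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(rate)))
  }
  ct <- suppressWarnings(
    stats::cor.test(rate, intensity, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(rate))
}

#' Per-class intensity difference between ts and nts cohorts
#'
#' For every rate class populated by both cohorts, the signed difference of
#' mean intensities dfI = mean fI(ts) - mean fI(nts) is computed and sorted
#' by sign; classes with dfI = 0 enter neither sign group.
#'
#' @param class_table output of \code{\link{bin_rate_classes}} containing
#'   both cohorts.
#' @return a \code{cohort_comparison}: list with data.frame \code{diffs}
#'   (\code{class_index}, \code{rate_mid}, \code{fI_ts}, \code{fI_nts},
#'   \code{delta_fI}), counts \code{n_positive}, \code{n_negative}, and the
#'   \code{\link{chi_square_sign_test}} fields \code{chi_square},
#'   \code{p_value}.
#' @export
cohort_difference <- function(class_table) {
  ts <- class_table[class_table$cohort == "ts", , drop = FALSE]
  nts <- class_table[class_table$cohort == "nts", , drop = FALSE]
  common <- intersect(ts$class_index, nts$class_index)
  if (length(common) == 0) stop("no rate class holds both cohorts")
  ts <- ts[match(common, ts$class_index), ]
  nts <- nts[match(common, nts$class_index), ]
  diffs <- data.frame(class_index = common, rate_mid = ts$rate_mid,
                      fI_ts = ts$mean_fI, fI_nts = nts$mean_fI,
                      delta_fI = ts$mean_fI - nts$mean_fI)
  n_pos <- sum(diffs$delta_fI > 0)
  n_neg <- sum(diffs$delta_fI < 0)
  test <- if (n_pos + n_neg > 0) chi_square_sign_test(n_pos, n_neg)
          else list(chi_square = NA_real_, p_value = NA_real_)
  structure(list(diffs = diffs, n_positive = n_pos, n_negative = n_neg,
                 chi_square = test$chi_square, p_value = test$p_value),
            class = "cohort_comparison")
}

#' Chi-square test of positive vs negative sign counts
#'
#' Goodness-of-fit of the observed positive/negative counts against equal
#' expected counts, df = 1, no continuity correction:
#' chi2 = (n_pos - n_neg)^2 / (n_pos + n_neg).
#'
#' @param n_pos,n_neg non-negative counts, not both zero.
#' @return list with \code{chi_square}, \code{p_value}.
#' @export
chi_square_sign_test <- function(n_pos, n_neg) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be non-negative")
  n <- n_pos + n_neg
  if (n == 0) stop("both counts zero; test undefined")
  chi2 <- (n_pos - n_neg)^2 / n
  list(chi_square = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
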