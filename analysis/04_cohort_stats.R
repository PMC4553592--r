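#!/usr/bin/env Rscript
# Stage 4: cohort statistics.
#
# Per phase: every active square's flickering rate (Hz) and intensity
# fI = sum dlum / t_ref, relF occupancy fractions, 30 x 0.03 Hz rate
# classes with per-cohort mean fI +/- SEM, exponential fits
# y = a*exp(b*x) to the class means, Spearman rank correlation of rate
# vs intensity, and the signed per-class dfI = fI_ts - fI_nts comparison
# with its chi-square sign test.
#
# Reads:  results/run_config.yaml, results/events_filtered.csv,
#         results/partition.csv
# Writes: results/records_<phase>.csv, results/rate_classes_<phase>.csv,
#         results/cohort_summary.json

suppressPackageStartupMessages(library(beeshimmer))

config <- read_run_config("results/run_config.yaml")
events <- read_events("results/events_filtered.csv")
partition <- read.csv("results/partition.csv")
part <- cohort_partition(partition[partition$cohort == "ts", ],
                         partition[partition$cohort == "nts", ])
fps <- config$scene$fps

summary_out <- list()
for (ph in names(config$phases)) {
  iv <- config$phases[[ph]]
  t_ref <- (iv[2] - iv[1] + 1) / fps
  ev <- events[events$onset_frame >= iv[1] & events$onset_frame <= iv[2], ]
  rec <- rate_intensity_records(ev, part, t_ref, phase_label = ph)
  relF <- relf_metrics(ev[, c("row", "col")], part, nrow(partition))
  tab <- bin_rate_classes(rec)
  write.csv(rec, sprintf("results/records_%s.csv", ph), row.names = FALSE)
  write.csv(tab, sprintf("results/rate_classes_%s.csv", ph),
            row.names = FALSE)

  cat(sprintf("\n== phase %s (t_ref %.0f s, %d events) ==\n",
              ph, t_ref, nrow(ev)))
  cat(sprintf("relF total %.4f | ts %.4f | nts %.4f\n",
              relF$relF_total, relF$relF_ts, relF$relF_nts))

  fits <- list()
  for (co in c("ts", "nts")) {
    sub <- tab[tab$cohort == co & tab$mean_fI > 0, ]
    if (nrow(sub) >= 2) {
      f <- fit_exponential(sub$rate_mid, sub$mean_fI)
      fits[[co]] <- f[c("a", "b", "r_squared")]
      cat(sprintf("%s fit: y = %.4f * exp(%.3f x), R2 = %.3f (%d classes)\n",
                  co, f$a, f$b, f$r_squared, nrow(sub)))
    }
  }
  act <- rec[rec$n_events > 0, ]
  spear <- if (nrow(act) >= 3) {
    s <- spearman_rate_intensity(act$rate_hz, act$fI)
    cat(sprintf("Spearman rate~fI: rho = %.3f, P = %.3g (n = %d)\n",
                s$rho, s$p_value, s$n))
    s
  } else NULL
  cmp <- tryCatch(cohort_difference(tab), error = function(e) NULL)
  if (!is.null(cmp)) {
    cat(sprintf("dfI sign test: %d positive vs %d negative classes, chi2 = %.2f, P = %.3g\n",
                cmp$n_positive, cmp$n_negative, cmp$chi_square, cmp$p_value))
  }
  summary_out[[ph]] <- list(
    t_ref_s = t_ref, n_events = nrow(ev), relF = relF, fits = fits,
    spearman = spear,
    comparison = if (is.null(cmp)) NULL else
      list(n_positive = cmp$n_positive, n_negative = cmp$n_negative,
           chi_square = cmp$chi_square, p_value = cmp$p_value))
}

jsonlite::write_json(summary_out, "results/cohort_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nwritten: results/records_<phase>.csv,",
    "results/rate_classes_<phase>.csv, results/cohort_summary.json\n")
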