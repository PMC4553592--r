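test_that("flickering rate is events per second", {
  expect_equal(square_rate(0, 100), 0)
  expect_equal(square_rate(27, 200), 0.135)
  # 6 events per minute = 0.1 Hz
  expect_equal(square_rate(6, 60), 0.1)
  expect_equal(rate_per_min(6, 60), 6)
  expect_error(square_rate(1, 0), "positive")
})

test_that("flickering intensity fI is summed event dlum per reference time", {
  expect_equal(square_intensity(numeric(), 10), 0)
  expect_equal(square_intensity(c(3, 5), 4), 2)
  expect_equal(square_intensity(c(3, 5), 8), 1)  # doubling t_ref halves fI
  expect_error(square_intensity(1, 0), "positive")
})

test_that("relF metrics are additive fractions of the nest squares", {
  g <- build_grid(c(100, 100), 10)
  active <- apply_mask(g)
  # designed partition: first 30 squares ts, rest nts
  m <- pool_trigger_activity(
    data.frame(wave_id = 1, phase = "p", row = 1, col = 1), g)
  m$activity[,] <- 0
  m$activity[cbind(active$row[1:30] + 1, active$col[1:30] + 1)] <- 1
  part <- partition_cohorts(m, active)

  none <- relf_metrics(data.frame(row = integer(), col = integer()),
                       part, 100)
  expect_equal(none$relF_total, 0)

  flick <- rbind(part$ts[1:18, ], part$nts[1:22, ])
  r <- relf_metrics(flick, part, 100)
  expect_equal(r$relF_ts, 0.18)
  expect_equal(r$relF_nts, 0.22)
  expect_equal(r$relF_total, 0.40)
  expect_equal(r$relF_ts + r$relF_nts, r$relF_total)

  full <- relf_metrics(active, part, 100)
  expect_equal(full$relF_total, 1.0)
  expect_error(relf_metrics(flick, part, 0), "positive")
})

test_that("rate classes are half-open 0.03 Hz bins with per-cohort SEM", {
  rec <- data.frame(row = 0:5, col = 0,
                    cohort = c("ts", "ts", "ts", "nts", "nts", "nts"),
                    n_events = c(5, 5, 2, 1, 1, 0),
                    rate_hz = c(0.135, 0.14, 0.02, 0.02, 0.89, 0),
                    fI = c(2, 3, 1, 0.5, 4, 0), phase = "p")
  tab <- bin_rate_classes(rec)
  ts4 <- tab[tab$cohort == "ts" & tab$class_index == 4, ]
  expect_equal(ts4$n, 2)  # floor(0.135/0.03) = floor(0.14/0.03) = 4
  expect_equal(ts4$mean_fI, 2.5)
  expect_equal(ts4$sem_fI, sd(c(2, 3)) / sqrt(2))
  # single record: SEM reported as 0 with n = 1
  nts29 <- tab[tab$cohort == "nts" & tab$class_index == 29, ]
  expect_equal(nts29$n, 1)
  expect_equal(nts29$sem_fI, 0)
  # zero-rate squares are not compiled by default but occupy class 0 if kept
  expect_false(any(tab$n[tab$cohort == "nts"] > 2))
  tab0 <- bin_rate_classes(rec, drop_zero_rate = FALSE)
  expect_true(0 %in% tab0$class_index[tab0$cohort == "nts"])
  # rates beyond the top class are capped into class 29 with a warning
  rec$rate_hz[1] <- 1.5
  expect_warning(tabc <- bin_rate_classes(rec), "capped")
  expect_equal(max(tabc$class_index), 29)
  # binning conservation
  expect_equal(sum(tabc$n), sum(rec$rate_hz > 0))
})

test_that("the exponential fit recovers noiseless curves exactly", {
  x <- seq(0.015, 0.4, by = 0.03)
  y <- 0.037 * exp(15.457 * x)
  f <- fit_exponential(x, y)
  expect_equal(f$a, 0.037, tolerance = 1e-7)
  expect_equal(f$b, 15.457, tolerance = 1e-7)
  expect_equal(f$r_squared, 1.0, tolerance = 1e-12)

  cst <- fit_exponential(1:5, rep(2.5, 5))
  expect_equal(cst$b, 0, tolerance = 1e-12)
  expect_equal(cst$a, 2.5, tolerance = 1e-12)

  expect_warning(fd <- fit_exponential(c(1, 2, 3), c(0, 1, 2.718282)),
                 "dropped")
  expect_equal(fd$n_used, 2)
  expect_error(suppressWarnings(fit_exponential(c(1, 2), c(0, 1))), ">= 2")
})

test_that("the exponential fit recovers parameters from lognormal noise", {
  set.seed(8)
  x <- seq(0.015, 0.9, by = 0.03)
  errs <- replicate(20, {
    y <- 0.05 * exp(6 * x) * exp(rnorm(length(x), 0, 0.1))
    f <- fit_exponential(x, y)
    c(f$a, f$b)
  })
  expect_lt(abs(mean(errs[1, ]) - 0.05), 0.01)
  expect_lt(abs(mean(errs[2, ]) - 6), 0.5)
})

test_that("Spearman correlation matches the brute-force rank formula", {
  inc <- spearman_rate_intensity(1:10, (1:10)^2)
  expect_equal(inc$rho, 1)
  dec <- spearman_rate_intensity(1:10, -(1:10))
  expect_equal(dec$rho, -1)

  set.seed(14)
  for (i in 1:50) {
    x <- sample(0:5, 12, TRUE) + runif(12)
    y <- sample(0:5, 12, TRUE) + runif(12)
    got <- spearman_rate_intensity(x, y)
    expect_equal(got$rho, naive_spearman(x, y), tolerance = 1e-12)
  }
  expect_warning(flat <- spearman_rate_intensity(rep(1, 5), 1:5), "constant")
  expect_true(is.na(flat$rho))
  expect_error(spearman_rate_intensity(1:2, 1:2), ">= 3")
})

test_that("cohort differences are signed per rate class", {
  rec <- data.frame(row = rep(0:9, 2), col = rep(0:1, each = 10),
                    cohort = rep(c("ts", "nts"), each = 10),
                    n_events = 1,
                    rate_hz = rep(seq(0.01, 0.28, length.out = 10), 2),
                    fI = c(rep(3, 10), rep(3, 10)), phase = "p")
  same <- cohort_difference(bin_rate_classes(rec))
  expect_equal(same$n_positive, 0)
  expect_equal(same$n_negative, 0)

  rec$fI[rec$cohort == "ts"] <- 5
  up <- cohort_difference(bin_rate_classes(rec))
  expect_equal(up$n_negative, 0)
  expect_equal(up$n_positive, nrow(up$diffs))
  expect_true(up$p_value < 0.05)
})

test_that("the sign chi-square test follows the closed form", {
  eq <- chi_square_sign_test(15, 15)
  expect_equal(eq$chi_square, 0)
  expect_equal(eq$p_value, 1)

  sk <- chi_square_sign_test(25, 5)
  expect_equal(sk$chi_square, (25 - 5)^2 / 30)
  expect_equal(sk$chi_square, 13.3333, tolerance = 1e-4)
  expect_lt(sk$p_value, 0.001)

  one <- chi_square_sign_test(1, 0)
  expect_equal(one$chi_square, 1)
  expect_equal(one$p_value, pchisq(1, 1, lower.tail = FALSE))
  expect_equal(one$p_value, 0.3173, tolerance = 1e-4)

  expect_error(chi_square_sign_test(0, 0), "undefined")
})
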