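# Build a clean channel of Hann bursts at given centres/amplitudes.
hann_channel <- function(centres, amps, duration_s, fs = 250, width = 0.5,
                         noise_sd = 0) {
  n <- round(duration_s * fs)
  x <- stats::rnorm(n, 0, noise_sd)
  for (i in seq_along(centres)) {
    i0 <- max(1, ceiling((centres[i] - width / 2) * fs) + 1)
    i1 <- min(n, floor((centres[i] + width / 2) * fs) + 1)
    tt <- (seq(i0, i1) - 1) / fs - centres[i]
    x[i0:i1] <- x[i0:i1] + amps[i] * 0.5 * (1 + cos(pi * tt / (width / 2)))
  }
  x
}

test_that("normalization scales the tallest burst to 100% and is scale invariant", {
  x <- hann_channel(c(5, 10), c(4, 2), 15)
  ng <- normalize_neurogram(x, fs = 250)
  expect_equal(max(ng$samples), 100)
  b <- detect_bursts(ng, r_times = c(5, 10) - 1.3)
  expect_equal(sort(b$amplitude_pct), c(50, 100), tolerance = 1e-6)
  ng2 <- normalize_neurogram(17.3 * x, fs = 250)
  expect_equal(ng$samples, ng2$samples, tolerance = 1e-12)
})

test_that("an all-noise channel raises a detection error", {
  set.seed(1)
  x <- stats::rnorm(15000, 0, 0.05)
  expect_error(normalize_neurogram(x, fs = 250), "no bursts")
})

test_that("burst-to-cycle assignment respects the latency window and one-per-cycle rule", {
  # two candidate peaks in one cycle: the taller is retained
  x <- hann_channel(c(11.2, 11.45), c(3, 4), 20)
  ng <- normalize_neurogram(x, fs = 250)
  b <- detect_bursts(ng, r_times = c(10, 12))
  expect_equal(nrow(b), 1)
  expect_equal(b$cycle_index, 1L)
  expect_equal(b$amplitude_pct, 100)
  expect_equal(b$latency, 1.45, tolerance = 0.01)

  # a peak 0.3 s after the only R wave lies outside the latency window
  x2 <- hann_channel(c(10.3, 15.3), c(3, 4), 20)
  ng2 <- normalize_neurogram(x2, fs = 250)
  b2 <- detect_bursts(ng2, r_times = c(10, 14))
  expect_false(1L %in% b2$cycle_index)
  expect_equal(b2$cycle_index, 2L)  # 15.3 is 1.3 s after the second R
})

test_that("burst detection meets sensitivity and FDR bounds on a synthetic subject", {
  p <- subject_params(duration_s = 240, fs = 125, noise_sd = 0.125,
                      seed = 31)  # amplitude SNR 8
  sub <- generate_subject(p)
  r <- detect_r_waves(sub$record)
  ng <- normalize_neurogram(sub$record)
  b <- detect_bursts(ng, r)
  truth <- sub$truth$bursts[which(sub$truth$bursts$occurred), ]
  sens <- mean(vapply(truth$center_time,
                      function(ct) any(abs(b$peak_time - ct) < 0.2),
                      logical(1)))
  fdr <- mean(!vapply(b$peak_time,
                      function(pt) any(abs(truth$center_time - pt) < 0.2),
                      logical(1)))
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.05)
  # every retained latency lies inside the configured window
  expect_true(all(b$latency >= 0.8 & b$latency <= 1.8))
})

test_that("mean burst latency is the arithmetic mean and is recovered from synthetic data", {
  b <- tibble::tibble(latency = c(1.2, 1.4))
  expect_equal(mean_burst_latency(b), 1.3)
  expect_equal(mean_burst_latency(tibble::tibble(latency = 1.3)), 1.3)
  expect_error(mean_burst_latency(tibble::tibble(latency = numeric())),
               "no bursts")

  p <- quick_params(duration_s = 240, seed = 32)
  sub <- generate_subject(p)
  b2 <- detect_bursts(normalize_neurogram(sub$record),
                      detect_r_waves(sub$record))
  expect_lt(abs(mean_burst_latency(b2) - p$burst_latency_s), 0.02)
})

test_that("neurogram shifting moves samples backward and composes additively", {
  x <- numeric(2500)
  x[1001] <- 5  # impulse at 10.0 s at fs 100
  ng <- structure(list(samples = x, fs = 100, start_time = 0,
                       shift_applied = 0, noise_sd_pct = 1, smooth_s = 0.05),
                  class = "neurogram")
  expect_identical(shift_neurogram(ng, 0)$samples, x)
  s1 <- shift_neurogram(ng, 1.3)
  expect_equal(which(s1$samples == 5), 871)  # impulse now at 8.7 s
  expect_equal(s1$shift_applied, 1.3)
  expect_true(all(is.na(s1$samples[(2500 - 129):2500])))
  s2 <- shift_neurogram(shift_neurogram(ng, 0.4), 0.9)
  valid <- !is.na(s2$samples)
  expect_equal(s2$samples[valid], shift_neurogram(ng, 1.3)$samples[valid])
  expect_equal(s2$shift_applied, 1.3)
})

test_that("resting metrics arithmetic on constructed inputs", {
  cyc <- regular_cycles(15, period = 4)           # covers [0, 60]
  grid <- build_interval_grid(cyc)
  ng <- const_neurogram(10, 60)
  r_times <- seq(0.5, 59.5, by = 1)               # 60 heartbeats
  bursts <- tibble::tibble(peak_time = r_times[seq(1, 59, by = 2)])
  m <- resting_metrics(bursts, r_times, ng, grid)
  expect_equal(m$bursts_per_100hb, 50)
  expect_equal(m$bursts_per_min, 30)
  expect_equal(m$total_area_per_s, 10, tolerance = 0.01)

  none <- resting_metrics(tibble::tibble(peak_time = numeric()),
                          r_times, ng, grid)
  expect_equal(none$bursts_per_100hb, 0)
  expect_equal(none$bursts_per_min, 0)
})

test_that("burst frequency equals incidence times mean heart rate over 100", {
  p <- quick_params(duration_s = 180, seed = 33)
  sub <- generate_subject(p)
  r <- detect_r_waves(sub$record)
  ng <- normalize_neurogram(sub$record)
  b <- detect_bursts(ng, r)
  sh <- shift_neurogram(ng, mean_burst_latency(b))
  grid <- build_interval_grid(detect_resp_cycles(sub$record))
  m <- resting_metrics(b, r, sh, grid)
  hr_mean <- m$n_heartbeats / (m$window_s / 60)
  expect_equal(m$bursts_per_min, m$bursts_per_100hb * hr_mean / 100,
               tolerance = 1e-9)
})
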