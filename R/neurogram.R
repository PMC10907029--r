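#' Normalize the integrated neurogram to the tallest burst
#'
#' The baseline (median of the channel, which is dominated by sub-burst
#' samples at physiological burst incidences) is subtracted, baseline
#' noise SD is estimated robustly from the lower half of the sample
#' distribution (bursts contaminate only the upper tail), candidate burst
#' peaks are found, and the channel is scaled so the tallest burst peak
#' equals 100%.
#'
#' @param record An [msna_record()], a data frame plus `fs`, or a raw
#'   numeric MSNA vector plus `fs`.
#' @param snr_min Minimum candidate peak height in baseline-noise SDs.
#' @param smooth_s Moving-average width used for candidate detection, s.
#' @param fs Sample rate, required unless `record` is an [msna_record()].
#' @return An object of class `neurogram`: list with `samples` (% of
#'   tallest burst), `fs`, `start_time`, `shift_applied` (s, 0 here) and
#'   `noise_sd_pct` (baseline noise SD in % units).
#' @export
normalize_neurogram <- function(record, snr_min = 3, smooth_s = 0.05,
                                fs = NULL) {
  if (is.numeric(record) && is.null(dim(record))) {
    if (is.null(fs)) stop("`fs` must be supplied with a raw vector")
    x <- record
    t0 <- 0
  } else {
    record <- as_record(record, fs)
    x <- record_channel(record, "msna")
    fs <- record$fs
    t0 <- record$start_time
  }
  y <- x - stats::median(x)
  sigma <- robust_lower_sd(y)
  w <- max(1L, round(smooth_s * fs))
  ys <- moving_average(y, w)
  cand <- local_maxima_above(ys, snr_min * sigma)
  if (length(cand) == 0) {
    stop("no bursts detected in the MSNA channel; review the SNR threshold")
  }
  # scale by the raw peak near the tallest candidate (same refinement as
  # burst detection, so the tallest detected burst is exactly 100%)
  tallest <- max(vapply(cand, function(i) {
    max(y[max(1L, i - w):min(length(y), i + w)])
  }, numeric(1)))
  structure(list(
    samples = 100 * y / tallest,
    fs = fs,
    start_time = t0,
    shift_applied = 0,
    noise_sd_pct = 100 * sigma / tallest,
    smooth_s = smooth_s
  ), class = "neurogram")
}

#' @export
print.neurogram <- function(x, ...) {
  cat(sprintf(
    "<neurogram> %d samples at %g Hz, shift %.3f s, baseline noise %.2f%%\n",
    length(x$samples), x$fs, x$shift_applied, x$noise_sd_pct))
  invisible(x)
}

robust_lower_sd <- function(y) {
  med <- stats::median(y)
  lower <- y[y <= med] - med
  sd <- 1.4826 * stats::median(abs(lower))
  if (sd <= 0) sd <- stats::sd(y) * 0.1 + .Machine$double.eps
  sd
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1L
  k <- rep(1 / w, w)
  out <- stats::filter(x, k, sides = 2)
  out[is.na(out)] <- x[is.na(out)]
  as.numeric(out)
}

local_maxima_above <- function(x, threshold) {
  n <- length(x)
  ok <- x >= threshold
  ok[2:n] <- ok[2:n] & x[2:n] >= x[1:(n - 1)]
  ok[1:(n - 1)] <- ok[1:(n - 1)] & x[1:(n - 1)] > x[2:n]
  which(ok)
}

#' Detect pulse-synchronous MSNA bursts
#'
#' Candidate peaks (local maxima of the lightly smoothed normalized
#' neurogram at least `snr_min` baseline-noise SDs above baseline) are
#' assigned to the most recent R wave whose lag falls inside
#' `latency_window`; candidates outside the window for every R wave are
#' rejected, and at most one burst (the tallest) is kept per cardiac
#' cycle. The default window 0.8-1.8 s brackets the peroneal conduction
#' delay.
#'
#' @param neurogram A [normalize_neurogram()] result (unshifted).
#' @param r_times R-wave times, s.
#' @param snr_min Minimum peak height in baseline-noise SDs.
#' @param latency_window Allowed R-wave-to-burst-peak lag, s (length 2).
#' @return A tibble with one row per burst: `burst`, `peak_time` (s,
#'   unshifted), `cycle_index`, `latency` (s), `amplitude_pct` (% of the
#'   tallest burst; the tallest burst is exactly 100).
#' @export
detect_bursts <- function(neurogram, r_times, snr_min = 3,
                          latency_window = c(0.8, 1.8)) {
  stopifnot(inherits(neurogram, "neurogram"), length(r_times) >= 1)
  y <- neurogram$samples
  fs <- neurogram$fs
  t0 <- neurogram$start_time
  ys <- moving_average(y, max(1L, round(neurogram$smooth_s * fs)))
  cand <- local_maxima_above(ys, snr_min * neurogram$noise_sd_pct)
  empty <- tibble::tibble(burst = integer(), peak_time = numeric(),
                          cycle_index = integer(), latency = numeric(),
                          amplitude_pct = numeric())
  if (length(cand) == 0) return(empty)

  # refine peak position and amplitude on the unsmoothed trace
  half <- max(1L, round(neurogram$smooth_s * fs))
  peak_idx <- vapply(cand, function(i) {
    i0 <- max(1L, i - half)
    i1 <- min(length(y), i + half)
    as.integer(i0 + which.max(y[i0:i1]) - 1L)
  }, integer(1))
  peak_idx <- unique(peak_idx)
  pt <- t0 + (peak_idx - 1) / fs

  k <- findInterval(pt, r_times)
  assign_cycle <- function(tt, k) {
    for (kk in c(k, k - 1L)) {
      if (kk >= 1 && kk <= length(r_times)) {
        lag <- tt - r_times[kk]
        if (lag >= latency_window[1] && lag <= latency_window[2]) return(kk)
      }
    }
    NA_integer_
  }
  cyc <- mapply(assign_cycle, pt, k)
  ok <- !is.na(cyc)
  if (!any(ok)) return(empty)

  tibble::tibble(peak_time = pt[ok],
                 cycle_index = as.integer(cyc[ok]),
                 amplitude_pct = y[peak_idx[ok]]) |>
    dplyr::group_by(.data$cycle_index) |>
    dplyr::slice_max(.data$amplitude_pct, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$peak_time) |>
    dplyr::mutate(burst = dplyr::row_number(),
                  latency = .data$peak_time - r_times[.data$cycle_index]) |>
    dplyr::select("burst", "peak_time", "cycle_index", "latency",
                  "amplitude_pct")
}

#' Mean burst latency
#'
#' Arithmetic mean of the R-wave-to-burst-peak delays; used to shift the
#' neurogram backward so bursts align with their cardiac cycle of origin.
#'
#' @param bursts Burst table from [detect_bursts()].
#' @return Mean latency, s.
#' @export
mean_burst_latency <- function(bursts) {
  if (nrow(bursts) == 0) stop("no bursts: latency undefined")
  mean(bursts$latency)
}

#' Shift a neurogram backward in time
#'
#' The output sample at time `t` equals the input at `t + shift_s` (shift
#' is rounded to whole samples); the trailing region beyond the record is
#' marked invalid (`NA`). Shifts compose additively.
#'
#' @param neurogram A `neurogram` object.
#' @param shift_s Backward shift, s (>= 0).
#' @return The shifted `neurogram` with `shift_applied` updated.
#' @export
shift_neurogram <- function(neurogram, shift_s) {
  stopifnot(inherits(neurogram, "neurogram"), shift_s >= 0)
  k <- round(shift_s * neurogram$fs)
  n <- length(neurogram$samples)
  if (k > 0) {
    neurogram$samples <- c(neurogram$samples[(k + 1):n], rep(NA_real_, k))
  }
  neurogram$shift_applied <- neurogram$shift_applied + k / neurogram$fs
  neurogram
}

# Integral of the neurogram (% . s) over [t0w, t1w), half-open in samples.
integrate_neurogram <- function(neurogram, t0w, t1w) {
  fs <- neurogram$fs
  i0 <- max(1L, floor((t0w - neurogram$start_time) * fs + 1e-9) + 1L)
  i1 <- min(length(neurogram$samples),
            ceiling((t1w - neurogram$start_time) * fs - 1e-9))
  if (i1 < i0) return(0)
  sum(neurogram$samples[i0:i1], na.rm = TRUE) / fs
}

#' Resting MSNA metrics over an analysis window
#'
#' MSNA is expressed as bursts/100 heartbeats, bursts/min and total burst
#' area/s. The area term sums the normalized shifted neurogram's integral
#' across the respiratory interval grid and divides by the window
#' duration, so its units are % of the tallest burst.
#'
#' @param bursts Burst table (unshifted peak times; the neurogram's
#'   `shift_applied` is subtracted internally).
#' @param r_times R-wave times, s.
#' @param neurogram Shifted normalized neurogram.
#' @param grid Interval grid from [build_interval_grid()]; defines the
#'   analysis window.
#' @return One-row tibble: `n_bursts`, `n_heartbeats`, `window_s`,
#'   `bursts_per_100hb`, `bursts_per_min`, `total_area_per_s`.
#' @export
resting_metrics <- function(bursts, r_times, neurogram, grid) {
  g <- grid[!grid$excluded, ]
  if (nrow(g) == 0) stop("empty interval grid")
  w0 <- min(g$t_start)
  w1 <- max(g$t_end)
  window_s <- sum(g$duration)
  hb <- sum(r_times >= w0 & r_times < w1)
  if (hb == 0) stop("no heartbeats in the analysis window")
  bt <- bursts$peak_time - neurogram$shift_applied
  nb <- sum(bt >= w0 & bt < w1)
  area <- sum(purrr::map2_dbl(g$t_start, g$t_end,
                              ~ integrate_neurogram(neurogram, .x, .y)))
  tibble::tibble(
    n_bursts = nb,
    n_heartbeats = hb,
    window_s = window_s,
    bursts_per_100hb = 100 * nb / hb,
    bursts_per_min = nb / (window_s / 60),
    total_area_per_s = area / window_s
  )
}
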