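#' Detect R-wave times from the ECG channel
#'
#' Threshold-and-local-maximum detector with a refractory constraint: of
#' any two detections closer than `refractory_s`, the taller is kept.
#' Externally supplied annotations pass through unchanged (sorted), which
#' is the route for recordings where R times were marked upstream.
#'
#' @param record An [msna_record()] (or data frame plus `fs`).
#' @param annotations Optional numeric vector of R-wave times, s; when
#'   given, detection is skipped.
#' @param threshold_frac Detection threshold as a fraction of the channel
#'   maximum.
#' @param refractory_s Minimum separation between detections, s.
#' @param fs Sample rate, required only for plain data frames.
#' @return Strictly increasing numeric vector of R-wave times, s.
#' @export
detect_r_waves <- function(record, annotations = NULL,
                           threshold_frac = 0.5, refractory_s = 0.25,
                           fs = NULL) {
  if (!is.null(annotations)) {
    return(sort(as.numeric(annotations)))
  }
  record <- as_record(record, fs)
  x <- record_channel(record, "ecg")
  thr <- threshold_frac * max(x)
  if (!is.finite(thr) || max(x) <= 0) stop("ECG channel unusable: no positive deflection")
  n <- length(x)
  is_max <- x >= thr
  is_max[2:n] <- is_max[2:n] & x[2:n] >= x[1:(n - 1)]
  is_max[1:(n - 1)] <- is_max[1:(n - 1)] & x[1:(n - 1)] > x[2:n]
  idx <- which(is_max)
  if (length(idx) == 0) stop("ECG channel unusable: no R waves detected")
  # refractory pass: among close detections keep the taller
  keep <- integer(0)
  min_gap <- refractory_s * record$fs
  for (i in idx) {
    if (length(keep) == 0 || i - keep[length(keep)] >= min_gap) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  record$start_time + (keep - 1) / record$fs
}

#' Beat-to-beat hemodynamics from the arterial pressure waveform
#'
#' For every cardiac cycle, the diastolic point is the pressure minimum in
#' a search window anchored at the R wave (`[r - diastole_pre_s,
#' r + diastole_post_frac * RR]`); systolic pressure is the maximum and
#' mean arterial pressure the mean of the waveform between adjacent
#' diastolic points (the waveform "modulus"). Heart rate is `60 / RR`,
#' time-stamped at the first R wave of each pair.
#'
#' @inheritParams detect_r_waves
#' @param r_times R-wave times from [detect_r_waves()].
#' @param diastole_pre_s,diastole_post_frac Diastolic search window bounds.
#' @return A tibble with one row per complete cardiac cycle (`length(r_times) - 1`
#'   rows): `beat`, `r_time`, `rr`, `hr`, `t_dbp`, `dbp`, `sbp`, `pp`, `map`.
#' @export
beat_hemodynamics <- function(record, r_times, diastole_pre_s = 0.1,
                              diastole_post_frac = 0.4, fs = NULL) {
  record <- as_record(record, fs)
  if (length(r_times) < 2) stop("need at least two R waves")
  p <- record_channel(record, "pressure")
  if (diff(range(p)) < 1) stop("pressure channel flat (range < 1 mmHg)")
  fs <- record$fs
  t0 <- record$start_time
  n <- length(p)
  nr <- length(r_times)
  rr_all <- diff(r_times)
  rr_search <- c(rr_all, rr_all[nr - 1])

  d_idx <- integer(nr)
  for (i in seq_len(nr)) {
    i0 <- max(1L, floor((r_times[i] - diastole_pre_s - t0) * fs) + 1L)
    i1 <- min(n, ceiling((r_times[i] + diastole_post_frac * rr_search[i] - t0) * fs) + 1L)
    d_idx[i] <- i0 + which.min(p[i0:i1]) - 1L
  }
  nb <- nr - 1
  sbp <- map <- numeric(nb)
  for (i in seq_len(nb)) {
    seg <- p[d_idx[i]:(d_idx[i + 1] - 1L)]
    sbp[i] <- max(seg)
    map[i] <- mean(seg)
  }
  dbp <- p[d_idx[seq_len(nb)]]
  tibble::tibble(
    beat = seq_len(nb),
    r_time = r_times[-nr],
    rr = rr_all,
    hr = 60 / rr_all,
    t_dbp = t0 + (d_idx[seq_len(nb)] - 1) / fs,
    dbp = dbp,
    sbp = sbp,
    pp = sbp - dbp,
    map = map
  )
}

# Local extrema of a series; flat stretches inherit the preceding slope
# so plateaus yield a single turning point.
local_extrema <- function(x) {
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) == 0) return(list(idx = integer(0), type = character(0)))
  pos <- cumsum(d != 0)
  filled <- c(d[nz[1]], d[nz])[pos + 1]  # forward fill; leading flats take first slope
  turns <- which(diff(filled) != 0) + 1L
  type <- ifelse(filled[turns] < filled[turns - 1L], "peak", "trough")
  list(idx = turns, type = type)
}

#' Detect respiratory cycles (trough/peak landmarks)
#'
#' The respiration trace is zero-phase low-pass filtered, alternating
#' trough/peak extrema are found, small-prominence wiggles are pruned, and
#' landmark times are refined on the unfiltered trace. Inspiration is
#' trough to peak; expiration is peak to trough. Incomplete first/last
#' breaths are discarded.
#'
#' @inheritParams detect_r_waves
#' @param lowpass_hz Low-pass cutoff before extremum detection, Hz.
#' @param prominence_frac Trough-to-peak excursions smaller than this
#'   fraction of the largest excursion are pruned as noise.
#' @return A tibble with one row per complete breath: `breath`,
#'   `t_trough`, `t_peak`, `t_trough_next`, `insp_dur`, `exp_dur`, `amp`
#'   (trace units) and `amp_norm` (% of the largest breath).
#' @export
detect_resp_cycles <- function(record, lowpass_hz = 1,
                               prominence_frac = 0.2, fs = NULL) {
  record <- as_record(record, fs)
  x <- record_channel(record, "respiration")
  fs <- record$fs
  ny <- fs / 2
  xs <- if (lowpass_hz < ny) {
    bf <- signal::butter(2, lowpass_hz / ny)
    as.numeric(signal::filtfilt(bf, x))
  } else x

  ext <- local_extrema(xs)
  idx <- ext$idx
  type <- ext$type
  # enforce alternation: in runs of same type keep the more extreme
  enforce <- function(idx, type) {
    keep <- rep(TRUE, length(idx))
    i <- 1
    while (i < length(idx)) {
      j <- i + 1
      while (j <= length(idx) && !keep[j]) j <- j + 1
      if (j > length(idx)) break
      if (type[i] == type[j]) {
        better_j <- if (type[i] == "peak") xs[idx[j]] > xs[idx[i]] else xs[idx[j]] < xs[idx[i]]
        if (better_j) { keep[i] <- FALSE; i <- j } else keep[j] <- FALSE
      } else i <- j
    }
    list(idx = idx[keep], type = type[keep])
  }
  e <- enforce(idx, type)
  # prune low-prominence adjacent pairs, then re-enforce alternation
  repeat {
    if (length(e$idx) < 3) break
    excur <- abs(diff(xs[e$idx]))
    lim <- prominence_frac * max(excur)
    small <- which(excur < lim)
    if (length(small) == 0) break
    s <- small[which.min(excur[small])]
    drop <- c(s, s + 1)
    e <- enforce(e$idx[-drop], e$type[-drop])
  }
  idx <- e$idx; type <- e$type
  # filter edge transients can fabricate extrema near the record bounds
  guard <- round(0.75 / lowpass_hz * fs)
  inb <- idx > guard & idx <= length(x) - guard
  idx <- idx[inb]; type <- type[inb]
  # refine on the raw trace within +/- 0.3 s
  half <- max(1L, round(0.3 * fs))
  for (i in seq_along(idx)) {
    i0 <- max(1L, idx[i] - half)
    i1 <- min(length(x), idx[i] + half)
    idx[i] <- i0 + (if (type[i] == "peak") which.max(x[i0:i1]) else which.min(x[i0:i1])) - 1L
  }

  tr <- idx[type == "trough"]
  pk <- idx[type == "peak"]
  # complete breaths: trough -> peak -> trough
  breaths <- list()
  for (k in seq_along(tr)[-length(tr)]) {
    p_in <- pk[pk > tr[k] & pk < tr[k + 1]]
    if (length(p_in) == 1) {
      breaths[[length(breaths) + 1]] <- c(tr[k], p_in, tr[k + 1])
    }
  }
  if (length(breaths) < 2) stop("fewer than two complete breaths detected")
  bm <- do.call(rbind, breaths)
  tt <- record$start_time + (bm - 1) / fs
  amp <- x[bm[, 2]] - (x[bm[, 1]] + x[bm[, 3]]) / 2
  tibble::tibble(
    breath = seq_len(nrow(bm)),
    t_trough = tt[, 1],
    t_peak = tt[, 2],
    t_trough_next = tt[, 3],
    insp_dur = tt[, 2] - tt[, 1],
    exp_dur = tt[, 3] - tt[, 2],
    amp = amp,
    amp_norm = 100 * amp / max(amp)
  )
}

#' Breathing rate and normalized respiratory amplitude over a window
#'
#' @param cycles Breath table from [detect_resp_cycles()].
#' @param window_duration Window length in seconds; defaults to the span
#'   of the detected breaths.
#' @return A one-row tibble: `n_breaths`, `breaths_per_min`,
#'   `mean_amp_norm` (%).
#' @export
respiratory_summary <- function(cycles, window_duration = NULL) {
  stopifnot(nrow(cycles) >= 1)
  if (is.null(window_duration)) {
    window_duration <- max(cycles$t_trough_next) - min(cycles$t_trough)
  }
  tibble::tibble(
    n_breaths = nrow(cycles),
    breaths_per_min = nrow(cycles) / (window_duration / 60),
    mean_amp_norm = mean(100 * cycles$amp / max(cycles$amp))
  )
}
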