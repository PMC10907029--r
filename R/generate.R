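#' Generate a respiratory transducer trace with known landmarks
#'
#' Breath periods are drawn around `breath_period_mean` with coefficient of
#' variation `breath_period_cv`; each breath rises trough-to-peak over
#' `insp_fraction` of its period and falls peak-to-trough over the rest,
#' both as raised-cosine segments (smooth at the landmarks, so trough and
#' peak are unambiguous for landmark-recovery tests). Per-breath amplitude
#' varies with CV `breath_amp_cv`.
#'
#' @param params A [subject_params()] object.
#' @param seed Integer seed for this channel's stream.
#' @return A list with `respiration` (numeric vector of length
#'   `round(duration_s * fs)`, arbitrary units), `landmarks` (tibble with
#'   one row per complete breath: `breath`, `t_trough`, `t_peak`,
#'   `t_trough_next`, `amplitude`), and `breaths` (the internal breath table
#'   including the partial breath covering the record tail, used to extend
#'   the respiratory phase beyond the last complete breath).
#' @export
generate_respiration <- function(params, seed = params$seed) {
  validate_subject_params(params)
  set.seed(seed)
  Tm <- params$breath_period_mean
  # draw breaths until they cover the record (plus one spare)
  periods <- numeric(0)
  while (sum(periods) < params$duration_s + Tm) {
    periods <- c(periods,
                 pmax(0.3 * Tm,
                      stats::rnorm(16, Tm, params$breath_period_cv * Tm)))
  }
  amps <- pmax(0.1, stats::rnorm(length(periods), 1, params$breath_amp_cv))
  troughs <- c(0, cumsum(periods))
  peaks <- troughs[-length(troughs)] + params$insp_fraction * periods

  n <- round(params$duration_s * params$fs)
  if (params$duration_s < periods[1]) {
    stop("record shorter than one breath: degenerate input")
  }
  t <- (seq_len(n) - 1) / params$fs
  k <- findInterval(t, troughs)
  k[k < 1] <- 1L
  k[k > length(periods)] <- length(periods)
  u <- (t - troughs[k]) / periods[k]
  f <- params$insp_fraction
  x <- ifelse(u < f,
              amps[k] * (1 - cos(pi * u / f)) / 2,
              amps[k] * (1 + cos(pi * (u - f) / (1 - f))) / 2)

  complete <- which(troughs[-1] <= params$duration_s + 1e-9)
  if (length(complete) < 1) {
    stop("record shorter than one breath: degenerate input")
  }
  landmarks <- tibble::tibble(
    breath = seq_along(complete),
    t_trough = troughs[complete],
    t_peak = peaks[complete],
    t_trough_next = troughs[complete + 1],
    amplitude = amps[complete]
  )
  breaths <- tibble::tibble(
    t_trough = troughs[-length(troughs)],
    period = periods,
    t_peak = peaks
  )
  list(respiration = x, landmarks = landmarks, breaths = breaths)
}

# Respiratory phase in [0, 1) at arbitrary times, extended cyclically
# beyond the covered breaths using the edge breath's period.
resp_phase_fun <- function(landmarks) {
  troughs <- c(landmarks$t_trough, landmarks$t_trough_next[nrow(landmarks)])
  periods <- diff(troughs)
  function(tt) {
    ph <- numeric(length(tt))
    k <- findInterval(tt, troughs)
    inside <- k >= 1 & k <= length(periods)
    ph[inside] <- (tt[inside] - troughs[k[inside]]) / periods[k[inside]]
    before <- k < 1
    ph[before] <- ((tt[before] - troughs[1]) / periods[1]) %% 1
    after <- k > length(periods)
    pl <- periods[length(periods)]
    ph[after] <- ((tt[after] - troughs[length(troughs)]) / pl) %% 1
    ph
  }
}

#' Generate R-wave times and an arterial pressure channel
#'
#' Instantaneous heart rate is `hr_base + (rsa_amp / 2) * m(t)` with
#' `m(t) = -cos(2 * pi * phase(t))`, where `phase` is the position within
#' the current breath; R-wave times are obtained by integrating this rate.
#' Each beat's pressure waveform rises diastole-to-systole as a raised
#' cosine over 0.3 of the R-R interval and decays linearly to the next
#' diastole. Per-beat diastolic pressure carries the Traube-Hering offset
#' `(th_amp / 2) * m(t - th_lag_s)` and systolic pressure is solved so the
#' beat's waveform mean (the MAP "modulus") equals the baseline MAP plus
#' exactly that offset.
#'
#' @param params A [subject_params()] object.
#' @param resp_landmarks Landmark tibble from [generate_respiration()].
#' @return A list with `r_times` (s), `pressure` (mmHg, length
#'   `round(duration_s * fs)`), `beats` (tibble of per-beat ground truth for
#'   every complete cardiac cycle: `r_time`, `rr`, `hr`, `dbp`, `sbp`,
#'   `map`), and `dbp_at_r` (true diastolic pressure for every R wave,
#'   including the last).
#' @export
generate_cardiac <- function(params, resp_landmarks) {
  validate_subject_params(params)
  if (params$hr_base <= 0) stop("hr_base must be positive")
  n <- round(params$duration_s * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  phase <- resp_phase_fun(resp_landmarks)
  m <- function(tt) -cos(2 * pi * phase(tt))

  hr_t <- params$hr_base + params$rsa_amp / 2 * m(t)
  beats_cum <- cumsum(hr_t / (60 * params$fs))
  nb <- floor(max(beats_cum))
  if (nb < 2) stop("record too short for two cardiac cycles")
  r_times <- stats::approx(beats_cum, t, xout = seq_len(nb))$y

  delta <- params$th_amp / 2 * m(r_times - params$th_lag_s)
  dbp <- params$dbp_base + delta
  map_base <- (params$dbp_base + params$sbp_base) / 2
  map_target <- map_base + delta
  rr_pad <- function(r) if (length(r) > 1) r[2] - r[1] else 1
  dbp_next <- c(dbp[-1], dbp[nb])
  # waveform mean = 0.15*DBP_i + 0.5*SBP_i + 0.35*DBP_{i+1}
  sbp <- (map_target - 0.15 * dbp - 0.35 * dbp_next) / 0.5

  # pad before the first beat with a decaying tail so the first diastolic
  # minimum sits at the first R wave, as it would mid-recording
  pressure <- dbp[1] + pmax(0, (sbp[1] - dbp[1]) * (r_times[1] - t) / rr_pad(r_times))
  idx_r <- pmin(pmax(round(r_times * params$fs) + 1, 1), n)
  for (i in seq_len(nb - 1)) {
    i0 <- idx_r[i]
    i1 <- idx_r[i + 1] - 1L
    if (i1 < i0) next
    tt <- t[i0:i1] - r_times[i]
    rr <- r_times[i + 1] - r_times[i]
    rise <- 0.3 * rr
    seg <- ifelse(tt < rise,
                  dbp[i] + (sbp[i] - dbp[i]) * (1 - cos(pi * tt / rise)) / 2,
                  sbp[i] + (dbp[i + 1] - sbp[i]) * (tt - rise) / (rr - rise))
    pressure[i0:i1] <- seg
  }
  if (idx_r[nb] <= n) pressure[idx_r[nb]:n] <- dbp[nb]

  rr <- diff(r_times)
  beats <- tibble::tibble(
    beat = seq_len(nb - 1),
    r_time = r_times[-nb],
    rr = rr,
    hr = 60 / rr,
    dbp = dbp[-nb],
    sbp = sbp[-nb],
    map = map_target[-nb]
  )
  list(r_times = r_times, pressure = pressure, beats = beats,
       dbp_at_r = dbp)
}

# Composite-window membership of a time given breath landmarks:
# inspiration/postinspiration = insp 60-100% + exp 0-60%;
# mid-late expiration = exp 60-100% + following insp 0-60%.
phase_window_of <- function(tt, landmarks) {
  out <- rep(NA_character_, length(tt))
  for (k in seq_len(nrow(landmarks))) {
    b <- landmarks[k, ]
    in_insp <- tt >= b$t_trough & tt < b$t_peak
    in_exp <- tt >= b$t_peak & tt < b$t_trough_next
    frac_i <- (tt - b$t_trough) / (b$t_peak - b$t_trough)
    frac_e <- (tt - b$t_peak) / (b$t_trough_next - b$t_peak)
    out[in_insp] <- ifelse(frac_i[in_insp] >= 0.6,
                           "inspiration_postinspiration", "mid_late_expiration")
    out[in_exp] <- ifelse(frac_e[in_exp] < 0.6,
                          "inspiration_postinspiration", "mid_late_expiration")
  }
  out
}

#' Generate an integrated MSNA neurogram with known burst truth
#'
#' For each cardiac cycle a burst occurs with probability
#' `clip(p_phase + (baro_slope / 100) * (DBP_prev - mean DBP), 0, 1)`:
#' `p_phase` is `burst_prob_insp` when the cycle's R wave falls in the
#' inspiration/postinspiration composite window of its breath, otherwise
#' `burst_prob_exp`, and `DBP_prev` is the previous cycle's diastolic
#' pressure (the baroreflex acts with a one-cycle delay, matching how the
#' analysis pairs each diastolic pressure with burst occurrence in the
#' following cycle). An occurring burst is a raised-cosine (Hann) pulse of
#' full width `burst_width_s` centred `burst_latency_s` after the R wave,
#' with amplitude drawn around `burst_amp_mean`; Gaussian noise of SD
#' `noise_sd` is added to the channel.
#'
#' @param params A [subject_params()] object.
#' @param r_times R-wave times, s.
#' @param resp_landmarks Landmark tibble from [generate_respiration()].
#' @param dbp_at_r True per-cycle diastolic pressure (same length as
#'   `r_times`).
#' @param seed Integer seed for this channel's stream.
#' @return A list with `msna` (volts, length `round(duration_s * fs)`) and
#'   `bursts`, a tibble with one row per cardiac cycle: `cycle`, `r_time`,
#'   `window` (composite-phase label, `NA` outside landmark coverage),
#'   `p`, `occurred`, `center_time` (R time + latency for occurring
#'   bursts), `amplitude`.
#' @export
generate_msna <- function(params, r_times, resp_landmarks, dbp_at_r,
                          seed = params$seed) {
  validate_subject_params(params)
  if (length(r_times) < 1) stop("r_times must be nonempty")
  stopifnot(length(dbp_at_r) == length(r_times))
  set.seed(seed)
  n <- round(params$duration_s * params$fs)
  nb <- length(r_times)

  window <- phase_window_of(r_times, resp_landmarks)
  p_phase <- ifelse(window == "inspiration_postinspiration",
                    params$burst_prob_insp, params$burst_prob_exp)
  dbp_prev <- c(dbp_at_r[1], dbp_at_r[-nb])
  p <- pmin(pmax(p_phase + params$baro_slope / 100 *
                   (dbp_prev - mean(dbp_at_r)), 0), 1)
  p[is.na(window)] <- 0
  occurred <- stats::runif(nb) < p
  amplitude <- ifelse(occurred,
                      pmax(0.05 * params$burst_amp_mean,
                           stats::rnorm(nb, params$burst_amp_mean,
                                        params$burst_amp_cv *
                                          params$burst_amp_mean)),
                      NA_real_)
  center <- ifelse(occurred, r_times + params$burst_latency_s, NA_real_)

  msna <- stats::rnorm(n, 0, params$noise_sd)
  half_w <- params$burst_width_s / 2
  for (i in which(occurred)) {
    i0 <- max(1L, ceiling((center[i] - half_w) * params$fs) + 1L)
    i1 <- min(n, floor((center[i] + half_w) * params$fs) + 1L)
    if (i1 < i0) next
    tt <- (seq(i0, i1) - 1) / params$fs - center[i]
    msna[i0:i1] <- msna[i0:i1] +
      amplitude[i] * 0.5 * (1 + cos(pi * tt / half_w))
  }

  bursts <- tibble::tibble(
    cycle = seq_len(nb), r_time = r_times, window = window,
    p = p, occurred = occurred, center_time = center, amplitude = amplitude
  )
  list(msna = msna, bursts = bursts)
}

#' Generate a complete synthetic subject recording
#'
#' Composes the respiration, cardiac and MSNA generators from one top-level
#' seed (`params$seed`), which spawns independent per-channel substreams.
#' The ECG channel is a unit impulse train at the R-wave times (burst
#' detection and beat segmentation only need the R fiducials).
#'
#' @param params A [subject_params()] object.
#' @return A list with `record` (an [msna_record()] with channels `ecg`,
#'   `pressure`, `respiration`, `msna`) and `truth`, a list holding
#'   `params`, `r_times`, `beats`, `resp_landmarks` and `bursts` ground
#'   truth.
#' @examples
#' sub <- generate_subject(subject_params(duration_s = 60, seed = 2))
#' sub$record
#' @export
generate_subject <- function(params) {
  validate_subject_params(params)
  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  resp <- generate_respiration(params, seed = sub_seeds[1])
  card <- generate_cardiac(params, resp$landmarks)
  msna <- generate_msna(params, card$r_times, resp$landmarks,
                        card$dbp_at_r, seed = sub_seeds[2])

  n <- round(params$duration_s * params$fs)
  ecg <- numeric(n)
  ecg[pmin(pmax(round(card$r_times * params$fs) + 1, 1), n)] <- 1

  record <- msna_record(
    tibble::tibble(ecg = ecg, pressure = card$pressure,
                   respiration = resp$respiration, msna = msna$msna),
    fs = params$fs
  )
  truth <- list(params = params, r_times = card$r_times,
                beats = card$beats, resp_landmarks = resp$landmarks,
                bursts = msna$bursts)
  list(record = record, truth = truth)
}

#' Generate a cohort of synthetic subjects
#'
#' @param group_specs A list of group specifications, each a list with
#'   `label` (character), `n` (subjects), `params` (a [subject_params()]
#'   template) and optionally `sd`, a named numeric vector of
#'   between-subject standard deviations for selected parameters (drawn
#'   normally around the template value; probabilities are clipped to
#'   \[0, 1\] and strictly positive parameters floored at 10% of the
#'   template).
#' @param seed Top-level integer seed; subject seeds are drawn from it.
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `params`, `record`, `truth` (the last three are list-columns).
#' @export
generate_cohort <- function(group_specs, seed = 1L) {
  if (length(group_specs) == 0) stop("group_specs must be nonempty")
  set.seed(seed)
  rows <- purrr::map(group_specs, function(g) {
    stopifnot(!is.null(g$label), !is.null(g$n), g$n >= 1,
              inherits(g$params, "subject_params"))
    purrr::map(seq_len(g$n), function(i) {
      p <- unclass(g$params)
      if (!is.null(g$sd)) {
        for (nm in names(g$sd)) {
          val <- stats::rnorm(1, p[[nm]], g$sd[[nm]])
          if (nm %in% c("burst_prob_exp", "burst_prob_insp")) {
            val <- min(max(val, 0), 1)
          } else if (p[[nm]] > 0) {
            val <- max(val, 0.1 * p[[nm]])
          }
          p[[nm]] <- val
        }
      }
      p$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      list(label = g$label, params = do.call(subject_params, p))
    })
  })
  rows <- purrr::flatten(rows)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_along(rows)),
    group = purrr::map_chr(rows, "label"),
    params = purrr::map(rows, "params"),
    subject = purrr::map(rows, ~ generate_subject(.x$params))
  ) |>
    dplyr::mutate(record = purrr::map(.data$subject, "record"),
                  truth = purrr::map(.data$subject, "truth")) |>
    dplyr::select(-"subject")
}
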