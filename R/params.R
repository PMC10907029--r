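#' Subject-level simulation parameters
#'
#' Bundles every generative constant behind a synthetic recording: cardiac
#' and respiratory rates, respiratory sinus arrhythmia (RSA) and
#' Traube-Hering (TH) modulation depths, phase-gated burst probabilities,
#' baroreflex gain, burst morphology and neurogram noise. Defaults emulate a
#' healthy resting adult in the semisupine position: heart rate near 60
#' beats/min, ~13-14 breaths/min, moderate inspiratory inhibition of MSNA
#' and a baroreflex gain of -5 % bursts/mmHg.
#'
#' @param duration_s Record length, seconds.
#' @param fs Sample rate, Hz (all four channels share it).
#' @param hr_base Baseline heart rate, beats/min.
#' @param rsa_amp Peak-to-peak respiratory swing of instantaneous heart
#'   rate, beats/min.
#' @param breath_period_mean,breath_period_cv Mean breath period (s) and its
#'   coefficient of variation across breaths.
#' @param insp_fraction Fraction of each breath spent in inspiration
#'   (trough to peak), in (0, 1).
#' @param breath_amp_cv Coefficient of variation of per-breath amplitude.
#' @param sbp_base,dbp_base Baseline systolic / diastolic pressure, mmHg.
#' @param th_amp Peak-to-peak respiratory swing of per-beat mean arterial
#'   pressure (Traube-Hering wave amplitude), mmHg.
#' @param th_lag_s Lag of the pressure modulation behind the respiratory
#'   phase, seconds.
#' @param burst_prob_exp,burst_prob_insp Per-cardiac-cycle burst probability
#'   when the R wave falls in the mid-late-expiration vs the
#'   inspiration/postinspiration composite window.
#' @param baro_slope Baroreflex gain: change in burst probability
#'   (percentage points) per mmHg of diastolic pressure; negative.
#' @param burst_latency_s Neural conduction delay from the R wave of the
#'   generating cycle to the burst peak in the integrated neurogram, s.
#' @param burst_width_s Full width of the raised-cosine burst pulse, s.
#' @param burst_amp_mean,burst_amp_cv Mean burst amplitude (V) and its
#'   coefficient of variation.
#' @param noise_sd Additive Gaussian neurogram noise SD, V.
#' @param seed Integer seed; one top-level seed spawns independent
#'   per-channel substreams.
#'
#' @return A validated list of class `subject_params`.
#' @seealso [generate_subject()]
#' @examples
#' p <- subject_params(duration_s = 120, seed = 1)
#' p$hr_base
#' @export
subject_params <- function(duration_s = 300,
                           fs = 250,
                           hr_base = 60,
                           rsa_amp = 6,
                           breath_period_mean = 4.4,
                           breath_period_cv = 0.1,
                           insp_fraction = 0.4,
                           breath_amp_cv = 0.15,
                           sbp_base = 125,
                           dbp_base = 72,
                           th_amp = 10,
                           th_lag_s = 0.5,
                           burst_prob_exp = 0.65,
                           burst_prob_insp = 0.35,
                           baro_slope = -5,
                           burst_latency_s = 1.3,
                           burst_width_s = 0.5,
                           burst_amp_mean = 1,
                           burst_amp_cv = 0.25,
                           noise_sd = 0.05,
                           seed = 1L) {
  p <- list(
    duration_s = duration_s, fs = fs, hr_base = hr_base, rsa_amp = rsa_amp,
    breath_period_mean = breath_period_mean,
    breath_period_cv = breath_period_cv, insp_fraction = insp_fraction,
    breath_amp_cv = breath_amp_cv, sbp_base = sbp_base, dbp_base = dbp_base,
    th_amp = th_amp, th_lag_s = th_lag_s, burst_prob_exp = burst_prob_exp,
    burst_prob_insp = burst_prob_insp, baro_slope = baro_slope,
    burst_latency_s = burst_latency_s, burst_width_s = burst_width_s,
    burst_amp_mean = burst_amp_mean, burst_amp_cv = burst_amp_cv,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

validate_subject_params <- function(p) {
  stopifnot(
    "duration_s must be > 0" = p$duration_s > 0,
    "fs must be > 0" = p$fs > 0,
    "hr_base must be > 0" = p$hr_base > 0,
    "rsa_amp must be >= 0" = p$rsa_amp >= 0,
    "breath_period_mean must be > 0" = p$breath_period_mean > 0,
    "breath_period_cv must be >= 0" = p$breath_period_cv >= 0,
    "insp_fraction must be in (0, 1)" =
      p$insp_fraction > 0 && p$insp_fraction < 1,
    "sbp_base must exceed dbp_base" = p$sbp_base > p$dbp_base,
    "th_amp must be >= 0" = p$th_amp >= 0,
    "burst probabilities must lie in [0, 1]" =
      p$burst_prob_exp >= 0 && p$burst_prob_exp <= 1 &&
        p$burst_prob_insp >= 0 && p$burst_prob_insp <= 1,
    "burst_latency_s must be >= 0" = p$burst_latency_s >= 0,
    "burst_width_s must be > 0" = p$burst_width_s > 0,
    "noise_sd must be >= 0" = p$noise_sd >= 0
  )
  invisible(p)
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>\n")
  cat(sprintf("  %.0f s at %g Hz, HR %g bpm (RSA %g bpm p-p), breaths %g s (CV %g)\n",
              x$duration_s, x$fs, x$hr_base, x$rsa_amp,
              x$breath_period_mean, x$breath_period_cv))
  cat(sprintf("  BP %g/%g mmHg, TH %g mmHg p-p (lag %g s)\n",
              x$sbp_base, x$dbp_base, x$th_amp, x$th_lag_s))
  cat(sprintf("  burst p (exp/insp) %g/%g, baro slope %g %%/mmHg, latency %g s\n",
              x$burst_prob_exp, x$burst_prob_insp, x$baro_slope,
              x$burst_latency_s))
  invisible(x)
}

#' Construct a synchronized multichannel recording object
#'
#' A lightweight container for synchronized, uniformly sampled channels
#' (`ecg`, `pressure`, `respiration`, `msna`). Analysis functions accept it
#' directly; the sample table is a tibble so the channels pipe into dplyr.
#'
#' @param data A data frame with column `t` (seconds) and one column per
#'   channel. Channels may be a subset of the canonical four.
#' @param fs Sample rate in Hz.
#' @param start_time Time of the first sample, seconds.
#' @return An object of class `msna_record` with elements `data`, `fs`,
#'   `start_time`.
#' @export
msna_record <- function(data, fs, start_time = 0) {
  stopifnot(is.data.frame(data), fs > 0)
  data <- tibble::as_tibble(data)
  if (!"t" %in% names(data)) {
    data <- dplyr::mutate(data,
                          t = start_time + (dplyr::row_number() - 1) / fs,
                          .before = 1)
  }
  structure(list(data = data, fs = fs, start_time = start_time),
            class = "msna_record")
}

#' @export
print.msna_record <- function(x, ...) {
  ch <- setdiff(names(x$data), "t")
  cat(sprintf("<msna_record> %d samples at %g Hz (%.1f s), channels: %s\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs,
              paste(ch, collapse = ", ")))
  invisible(x)
}

# Accept either an msna_record or a data frame + fs.
as_record <- function(record, fs = NULL) {
  if (inherits(record, "msna_record")) return(record)
  if (is.data.frame(record)) {
    if (is.null(fs)) stop("`fs` must be supplied when `record` is a plain data frame")
    return(msna_record(record, fs))
  }
  stop("`record` must be an msna_record or a data frame")
}

record_channel <- function(record, name) {
  if (!name %in% names(record$data)) {
    stop(sprintf("record has no '%s' channel", name))
  }
  record$data[[name]]
}
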