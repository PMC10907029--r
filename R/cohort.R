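#' Default analysis configuration
#'
#' Every tunable threshold of the pipeline in one list; any element can
#' be overridden by passing a partial list to [analyze_subject()].
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    r_waves = list(threshold_frac = 0.5, refractory_s = 0.25),
    beats = list(diastole_pre_s = 0.1, diastole_post_frac = 0.4),
    resp = list(lowpass_hz = 1, prominence_frac = 0.2),
    msna = list(snr_min = 3, latency_window = c(0.8, 1.8),
                smooth_s = 0.05),
    phases = list(artifact_pct = 150, expiration_pairing = "following"),
    sbrs = list(min_bins = 3, min_range_mmhg = 3),
    coupling = list(method = "pearson", lags = c(-1L, 0L, 1L))
  )
}

merge_config <- function(config) {
  base <- default_config()
  for (sec in names(config)) {
    for (key in names(config[[sec]])) base[[sec]][[key]] <- config[[sec]][[key]]
  }
  base
}

#' Analyze one subject end to end
#'
#' Runs the full per-subject pipeline: R-wave and respiratory landmark
#' detection, beat hemodynamics, neurogram normalization, burst detection
#' and latency shift, interval grid and composite phases, phase metrics
#' and modulation change, spontaneous sympathetic baroreflex sensitivity,
#' per-breath RSA / Traube-Hering / respiratory-modulated MSNA and their
#' lagged coupling. Any stage failure is recorded in `errors` and the
#' dependent summary fields are left `NA`; the function itself does not
#' throw, so a cohort run continues past a bad subject.
#'
#' @param record An [msna_record()].
#' @param config Partial configuration overriding [default_config()].
#' @param annotations Optional R-wave annotation times, s.
#' @return An object of class `subject_analysis`: list with `summary`
#'   (one-row tibble), the intermediate tables (`beats`, `cycles`,
#'   `bursts`, `phases`, `phase_metrics`, `change`, `sbrs`,
#'   `breath_table`, `coupling`) and `errors` (named character vector).
#' @export
analyze_subject <- function(record, config = list(), annotations = NULL) {
  cfg <- merge_config(config)
  errors <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  r_times <- stage("r_waves", detect_r_waves(
    record, annotations = annotations,
    threshold_frac = cfg$r_waves$threshold_frac,
    refractory_s = cfg$r_waves$refractory_s))
  beats <- stage("beats", beat_hemodynamics(
    record, r_times, diastole_pre_s = cfg$beats$diastole_pre_s,
    diastole_post_frac = cfg$beats$diastole_post_frac))
  cycles <- stage("resp_cycles", detect_resp_cycles(
    record, lowpass_hz = cfg$resp$lowpass_hz,
    prominence_frac = cfg$resp$prominence_frac))

  neuro <- stage("neurogram", normalize_neurogram(
    record, snr_min = cfg$msna$snr_min, smooth_s = cfg$msna$smooth_s))
  bursts <- if (!is.null(neuro) && !is.null(r_times)) {
    stage("bursts", detect_bursts(neuro, r_times,
                                  snr_min = cfg$msna$snr_min,
                                  latency_window = cfg$msna$latency_window))
  } else NULL
  latency <- if (!is.null(bursts) && nrow(bursts) > 0) {
    mean_burst_latency(bursts)
  } else NA_real_
  shifted <- if (!is.null(neuro) && is.finite(latency)) {
    shift_neurogram(neuro, latency)
  } else NULL

  grid <- if (!is.null(cycles)) stage("grid", build_interval_grid(cycles)) else NULL
  phases <- if (!is.null(grid)) {
    stage("phases", {
      ph <- assemble_phases(grid,
                            expiration_pairing = cfg$phases$expiration_pairing)
      if (!is.null(shifted)) {
        ph <- exclude_artifact_phases(ph, shifted,
                                      artifact_pct = cfg$phases$artifact_pct)
      }
      ph
    })
  } else NULL

  rest <- if (!is.null(bursts) && !is.null(r_times) && !is.null(shifted) &&
                !is.null(grid)) {
    stage("resting", resting_metrics(bursts, r_times, shifted, grid))
  } else NULL
  pmx <- if (!is.null(phases) && !is.null(bursts) && !is.null(r_times) &&
               !is.null(shifted)) {
    stage("phase_metrics", phase_metrics(phases, bursts, r_times, shifted))
  } else NULL
  chg <- if (!is.null(pmx) && nrow(pmx) == 2) {
    stage("modulation_change", modulation_change(pmx))
  } else NULL
  sb <- if (!is.null(beats) && !is.null(bursts) && !is.null(shifted)) {
    stage("sbrs", sbrs(beats, bursts, shifted,
                       min_bins = cfg$sbrs$min_bins,
                       min_range_mmhg = cfg$sbrs$min_range_mmhg))
  } else NULL
  breath_tab <- if (!is.null(beats) && !is.null(cycles)) {
    stage("breath_table",
          breath_hemodynamics(beats, cycles,
                              record_channel(record, "msna"),
                              fs = record$fs))
  } else NULL
  coup <- if (!is.null(breath_tab)) {
    stage("coupling", lagged_coupling(breath_tab$msna_resp, breath_tab$th,
                                      lags = cfg$coupling$lags,
                                      method = cfg$coupling$method))
  } else NULL

  pull_phase <- function(metric, label) {
    if (is.null(pmx)) return(NA_real_)
    v <- pmx[[metric]][pmx$label == label]
    if (length(v) == 1) v else NA_real_
  }
  pull_chg <- function(metric, col) {
    if (is.null(chg)) return(NA_real_)
    v <- chg[[col]][chg$metric == metric]
    if (length(v) == 1) v else NA_real_
  }
  pull_coup <- function(L, col) {
    if (is.null(coup)) return(NA)
    v <- coup[[col]][coup$lag == L]
    if (length(v) == 1) v else NA
  }
  resp_sum <- if (!is.null(cycles)) respiratory_summary(cycles) else NULL

  summary <- tibble::tibble(
    n_beats = if (is.null(beats)) NA_integer_ else nrow(beats),
    n_breaths = if (is.null(cycles)) NA_integer_ else nrow(cycles),
    hr_mean = if (is.null(beats)) NA_real_ else mean(beats$hr),
    sbp_mean = if (is.null(beats)) NA_real_ else mean(beats$sbp),
    dbp_mean = if (is.null(beats)) NA_real_ else mean(beats$dbp),
    pp_mean = if (is.null(beats)) NA_real_ else mean(beats$pp),
    map_mean = if (is.null(beats)) NA_real_ else mean(beats$map),
    breathing_rate = if (is.null(resp_sum)) NA_real_ else resp_sum$breaths_per_min,
    resp_amp_norm_mean = if (is.null(resp_sum)) NA_real_ else resp_sum$mean_amp_norm,
    mean_burst_latency_s = latency,
    bursts_per_100hb = if (is.null(rest)) NA_real_ else rest$bursts_per_100hb,
    bursts_per_min = if (is.null(rest)) NA_real_ else rest$bursts_per_min,
    total_area_per_s = if (is.null(rest)) NA_real_ else rest$total_area_per_s,
    incidence_exp = pull_phase("incidence", "mid_late_expiration"),
    incidence_insp = pull_phase("incidence", "inspiration_postinspiration"),
    frequency_exp = pull_phase("frequency", "mid_late_expiration"),
    frequency_insp = pull_phase("frequency", "inspiration_postinspiration"),
    total_area_exp = pull_phase("total_area_per_s", "mid_late_expiration"),
    total_area_insp = pull_phase("total_area_per_s", "inspiration_postinspiration"),
    mean_area_exp = pull_phase("mean_area_per_s", "mid_late_expiration"),
    mean_area_insp = pull_phase("mean_area_per_s", "inspiration_postinspiration"),
    incidence_abs_change = pull_chg("incidence", "abs_change"),
    incidence_pct_change = pull_chg("incidence", "pct_change"),
    frequency_abs_change = pull_chg("frequency", "abs_change"),
    frequency_pct_change = pull_chg("frequency", "pct_change"),
    total_area_pct_change = pull_chg("total_area_per_s", "pct_change"),
    mean_area_pct_change = pull_chg("mean_area_per_s", "pct_change"),
    sbrs_occurrence = if (is.null(sb)) NA_real_ else sb$occurrence$slope,
    sbrs_area = if (is.null(sb)) NA_real_ else sb$area$slope,
    rsa_mean = if (is.null(breath_tab)) NA_real_ else mean(breath_tab$rsa, na.rm = TRUE),
    th_mean = if (is.null(breath_tab)) NA_real_ else mean(breath_tab$th, na.rm = TRUE),
    msna_resp_mean = if (is.null(breath_tab)) NA_real_ else
      mean(breath_tab$msna_resp, na.rm = TRUE),
    coupling_r_lag0 = as.numeric(pull_coup(0L, "r")),
    coupling_p_lag0 = as.numeric(pull_coup(0L, "p_value")),
    coupling_sig_pos_lag0 = as.logical(pull_coup(0L, "significant_positive")),
    coupling_r_lag_m1 = as.numeric(pull_coup(-1L, "r")),
    coupling_r_lag_p1 = as.numeric(pull_coup(1L, "r")),
    n_errors = length(errors)
  )

  structure(list(summary = summary, beats = beats, cycles = cycles,
                 bursts = bursts, neurogram = shifted, grid = grid,
                 phases = phases, phase_metrics = pmx, change = chg,
                 sbrs = sb, breath_table = breath_tab, coupling = coup,
                 errors = errors),
            class = "subject_analysis")
}

#' @export
print.subject_analysis <- function(x, ...) {
  cat("<subject_analysis>\n")
  print(tibble::as_tibble(x$summary))
  if (length(x$errors) > 0) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

#' Analyze a cohort of recordings
#'
#' Applies [analyze_subject()] to each record of a cohort tibble (as
#' produced by [generate_cohort()], or any tibble with `subject_id`,
#' `group`, `record` columns) and binds the one-row summaries.
#'
#' @param cohort Cohort tibble with a `record` list-column.
#' @param config Passed to [analyze_subject()].
#' @param keep_analyses Keep the full per-subject analysis objects in a
#'   list-column `analysis`?
#' @return A tibble with one row per subject: `subject_id`, `group`, the
#'   summary columns, and optionally `analysis`.
#' @export
analyze_cohort <- function(cohort, config = list(), keep_analyses = FALSE) {
  analyses <- purrr::map(cohort$record, analyze_subject, config = config)
  out <- dplyr::bind_cols(
    cohort[, intersect(c("subject_id", "group"), names(cohort))],
    dplyr::bind_rows(purrr::map(analyses, "summary"))
  )
  if (keep_analyses) out$analysis <- analyses
  out
}

#' Long phase-metric table for the mixed ANOVA
#'
#' Reshapes an [analyze_cohort()] summary into subject x phase long
#' format for one metric.
#'
#' @param cohort_summary Output of [analyze_cohort()].
#' @param metric One of `"incidence"`, `"frequency"`, `"total_area"`,
#'   `"mean_area"`.
#' @return Long tibble: `subject_id`, `group`, `phase`, `value`.
#' @export
phase_long <- function(cohort_summary, metric = "incidence") {
  cols <- paste0(metric, c("_exp", "_insp"))
  stopifnot(all(cols %in% names(cohort_summary)))
  cohort_summary |>
    dplyr::select("subject_id", "group", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "phase",
                        values_to = "value") |>
    dplyr::mutate(phase = ifelse(endsWith(.data$phase, "_exp"),
                                 "mid_late_expiration",
                                 "inspiration_postinspiration"))
}
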