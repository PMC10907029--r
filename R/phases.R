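#' Divide each respiratory period into five equal intervals
#'
#' Every inspiratory and expiratory period is split into five contiguous,
#' equal-length intervals that tile the period exactly, giving ten
#' intervals per complete breath. Degenerate breaths (zero-length period)
#' are excluded with a reason but leave the rest of the grid valid.
#'
#' @param cycles Breath table from [detect_resp_cycles()] (columns
#'   `breath`, `t_trough`, `t_peak`, `t_trough_next`).
#' @return A tibble with one row per interval: `breath`, `period`
#'   (`"insp"`/`"exp"`), `interval` (1-5), `t_start`, `t_end`, `duration`,
#'   `excluded`, `reason`.
#' @export
build_interval_grid <- function(cycles) {
  stopifnot(nrow(cycles) >= 2)
  n <- nrow(cycles)
  breath <- rep(cycles$breath, each = 2)
  period <- rep(c("insp", "exp"), n)
  a <- as.vector(rbind(cycles$t_trough, cycles$t_peak))
  b <- as.vector(rbind(cycles$t_peak, cycles$t_trough_next))
  j <- rep(1:5, times = 2 * n)
  a5 <- rep(a, each = 5)
  len5 <- rep(b - a, each = 5)
  bad <- unique(breath[b <= a])
  g <- tibble::tibble(
    breath = rep(breath, each = 5),
    period = rep(period, each = 5),
    interval = j,
    t_start = a5 + (j - 1) / 5 * len5,
    t_end = a5 + j / 5 * len5
  )
  g$duration <- g$t_end - g$t_start
  g$excluded <- g$breath %in% bad
  g$reason <- ifelse(g$excluded, "zero_length_period", NA_character_)
  g
}

#' Assemble the two composite respiratory phases
#'
#' Inspiration/postinspiration of breath *k* is intervals 60-100% of its
#' inspiration plus 0-60% of its expiration; mid-late expiration is
#' intervals 60-100% of expiration plus 0-60% of the following breath's
#' inspiration (configurable to the same breath's inspiration via
#' `expiration_pairing = "same"`). With the default pairing the two phases
#' alternate contiguously across the record. Boundary instances missing
#' their cross-breath partner intervals are dropped, as are instances
#' touching an excluded (degenerate) breath.
#'
#' @param grid Interval grid from [build_interval_grid()].
#' @param expiration_pairing Which breath's early inspiration completes
#'   the mid-late-expiration phase: `"following"` (default) or `"same"`.
#' @return A tibble of class `phase_windows` with one row per member
#'   interval: `phase_id`, `label`, `anchor_breath`, `t_start`, `t_end`,
#'   `duration`, `excluded`, `reason`.
#' @export
assemble_phases <- function(grid, expiration_pairing = c("following", "same")) {
  expiration_pairing <- match.arg(expiration_pairing)
  g <- grid[!grid$excluded, ]
  ip <- g[(g$period == "insp" & g$interval >= 4) |
            (g$period == "exp" & g$interval <= 3), ]
  ip$anchor_breath <- ip$breath
  ip$label <- "inspiration_postinspiration"
  ip$phase_id <- sprintf("insp_post_%04d", ip$anchor_breath)

  me_exp <- g[g$period == "exp" & g$interval >= 4, ]
  me_exp$anchor_breath <- me_exp$breath
  me_insp <- g[g$period == "insp" & g$interval <= 3, ]
  me_insp$anchor_breath <- me_insp$breath -
    (if (expiration_pairing == "following") 1L else 0L)
  me <- dplyr::bind_rows(me_exp, me_insp)
  me$label <- "mid_late_expiration"
  me$phase_id <- sprintf("mid_late_exp_%04d", me$anchor_breath)

  res <- dplyr::bind_rows(ip, me)
  # keep only complete instances (all 5 member intervals present)
  counts <- table(res$phase_id)
  res <- res[res$phase_id %in% names(counts)[counts == 5], ]
  res <- res[order(res$t_start), ]
  res$excluded <- FALSE
  res$reason <- NA_character_
  res <- dplyr::select(res, "phase_id", "label", "anchor_breath", "breath",
                       "period", "interval", "t_start", "t_end", "duration",
                       "excluded", "reason")
  class(res) <- c("phase_windows", class(res))
  attr(res, "expiration_pairing") <- expiration_pairing
  res
}

#' Exclude phase instances aligned with neurogram artifacts
#'
#' A phase instance is excluded in full when any sample inside any of its
#' member intervals exceeds `artifact_pct` (% of the tallest burst) or
#' overlaps a user-supplied artifact mask.
#'
#' @param phases Phase windows from [assemble_phases()].
#' @param neurogram Normalized (shifted) neurogram.
#' @param artifact_pct Artifact amplitude threshold, % of tallest burst.
#' @param mask Optional tibble of artifact spans (`t_start`, `t_end`).
#' @return `phases` with `excluded`/`reason` set per phase instance.
#' @export
exclude_artifact_phases <- function(phases, neurogram, artifact_pct = 150,
                                    mask = NULL) {
  fs <- neurogram$fs
  t0 <- neurogram$start_time
  window_max <- function(a, b) {
    i0 <- max(1L, floor((a - t0) * fs) + 1L)
    i1 <- min(length(neurogram$samples), ceiling((b - t0) * fs))
    if (i1 < i0) return(-Inf)
    max(neurogram$samples[i0:i1], na.rm = TRUE)
  }
  for (id in unique(phases$phase_id)) {
    rows <- which(phases$phase_id == id)
    hit <- any(vapply(rows, function(r) {
      window_max(phases$t_start[r], phases$t_end[r]) > artifact_pct
    }, logical(1)))
    reason <- if (hit) "artifact_amplitude" else NA_character_
    if (!hit && !is.null(mask)) {
      hit <- any(vapply(rows, function(r) {
        any(phases$t_start[r] < mask$t_end & phases$t_end[r] > mask$t_start)
      }, logical(1)))
      if (hit) reason <- "artifact_mask"
    }
    if (hit) {
      phases$excluded[rows] <- TRUE
      phases$reason[rows] <- reason
    }
  }
  phases
}

# Assign event times to phase labels; returns NA for times outside all
# non-excluded member intervals. Intervals are half-open [start, end).
assign_phase <- function(times, phases) {
  ph <- phases[!phases$excluded, ]
  ph <- ph[order(ph$t_start), ]
  k <- findInterval(times, ph$t_start)
  lab <- rep(NA_character_, length(times))
  ok <- k >= 1
  ok[ok] <- times[ok] < ph$t_end[k[ok]]
  lab[ok] <- ph$label[k[ok]]
  lab
}

#' MSNA metrics per composite respiratory phase
#'
#' Bursts (latency-shifted peak times) and heartbeats (raw R times; only
#' the neurogram and bursts are shifted, which aligns bursts to their
#' cardiac cycle of origin) are assigned to the phase containing them.
#' Burst incidence is bursts/100 heartbeats, frequency bursts/min, total
#' area/s the summed neurogram integral over member intervals divided by
#' phase duration, and mean area/s the mean of per-interval area rates.
#'
#' @param phases Phase windows from [assemble_phases()] (after any
#'   artifact exclusion).
#' @param bursts Burst table from [detect_bursts()] (unshifted times; the
#'   neurogram's `shift_applied` is subtracted internally so both carry
#'   the same shift).
#' @param r_times R-wave times, s.
#' @param neurogram Shifted normalized neurogram.
#' @return A tibble of class `phase_metrics` with one row per phase label:
#'   `label`, `n_bursts`, `n_heartbeats`, `duration_s`, `incidence`
#'   (bursts/100 HB, `NA` when a phase holds no heartbeats), `frequency`
#'   (bursts/min), `total_area_per_s`, `mean_area_per_s` (%).
#' @export
phase_metrics <- function(phases, bursts, r_times, neurogram) {
  shift <- neurogram$shift_applied
  bt <- bursts$peak_time - shift
  burst_lab <- assign_phase(bt, phases)
  hb_lab <- assign_phase(r_times, phases)
  ph <- phases[!phases$excluded, ]
  ph$.area <- purrr::map2_dbl(ph$t_start, ph$t_end,
                              ~ integrate_neurogram(neurogram, .x, .y))
  res <- ph |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      duration_s = sum(.data$duration),
      total_area = sum(.data$.area),
      mean_area_per_s = mean(.data$.area / .data$duration),
      .groups = "drop") |>
    dplyr::mutate(
      n_bursts = vapply(.data$label, function(l) sum(burst_lab == l, na.rm = TRUE),
                        numeric(1), USE.NAMES = FALSE),
      n_heartbeats = vapply(.data$label, function(l) sum(hb_lab == l, na.rm = TRUE),
                            numeric(1), USE.NAMES = FALSE),
      incidence = ifelse(.data$n_heartbeats > 0,
                         100 * .data$n_bursts / .data$n_heartbeats, NA_real_),
      frequency = .data$n_bursts / (.data$duration_s / 60),
      total_area_per_s = .data$total_area / .data$duration_s
    ) |>
    dplyr::select("label", "n_bursts", "n_heartbeats", "duration_s",
                  "incidence", "frequency", "total_area_per_s",
                  "mean_area_per_s")
  class(res) <- c("phase_metrics", class(res))
  res
}

#' Change in MSNA metrics from mid-late expiration to inspiration/postinspiration
#'
#' Signed absolute and percent change for each phase metric; a negative
#' percent change is inspiratory inhibition. Percent change is undefined
#' (`NA`) when the expiratory-phase value is 0.
#'
#' @param metrics Phase metrics from [phase_metrics()].
#' @return A tibble: `metric`, `expiration`, `inspiration`, `abs_change`,
#'   `pct_change`.
#' @export
modulation_change <- function(metrics) {
  stopifnot(all(c("mid_late_expiration", "inspiration_postinspiration") %in%
                  metrics$label))
  exp_row <- metrics[metrics$label == "mid_late_expiration", ]
  insp_row <- metrics[metrics$label == "inspiration_postinspiration", ]
  vars <- c("incidence", "frequency", "total_area_per_s", "mean_area_per_s")
  tibble::tibble(
    metric = vars,
    expiration = as.numeric(exp_row[1, vars]),
    inspiration = as.numeric(insp_row[1, vars])
  ) |>
    dplyr::mutate(
      abs_change = .data$inspiration - .data$expiration,
      pct_change = ifelse(.data$expiration > 0,
                          100 * .data$abs_change / .data$expiration, NA_real_)
    )
}
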