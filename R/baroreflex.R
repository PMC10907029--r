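#' Per-beat table for spontaneous sympathetic baroreflex sensitivity
#'
#' For each cardiac cycle's diastolic pressure, records whether a burst
#' occurred in the following cardiac cycle and the mean of the normalized,
#' latency-shifted neurogram in a +/- 0.4 s window around the following
#' cycle's R wave.
#'
#' @param beats Beat table from [beat_hemodynamics()].
#' @param bursts Burst table from [detect_bursts()] (cycle indices refer
#'   to the same R-wave series as `beats`).
#' @param neurogram Shifted normalized neurogram.
#' @param area_halfwidth_s Half-width of the area sampling window, s.
#' @return A tibble: `beat`, `dbp`, `occurred_next` (0/1), `area_next`
#'   (%).
#' @export
build_baro_table <- function(beats, bursts, neurogram,
                             area_halfwidth_s = 0.4) {
  nb <- nrow(beats)
  if (nb < 1) stop("empty beat table")
  r_next <- beats$r_time + beats$rr
  burst_cycles <- unique(bursts$cycle_index)
  fs <- neurogram$fs
  t0 <- neurogram$start_time
  n <- length(neurogram$samples)
  area <- vapply(r_next, function(rt) {
    i0 <- max(1L, round((rt - area_halfwidth_s - t0) * fs) + 1L)
    i1 <- min(n, round((rt + area_halfwidth_s - t0) * fs) + 1L)
    if (i1 < i0) return(NA_real_)
    mean(neurogram$samples[i0:i1], na.rm = TRUE)
  }, numeric(1))
  out <- tibble::tibble(
    beat = beats$beat,
    dbp = beats$dbp,
    occurred_next = as.integer((beats$beat + 1L) %in% burst_cycles),
    area_next = area
  )
  out <- out[!is.na(out$area_next), ]
  if (nrow(out) < 10) stop("fewer than 10 usable beats for sBRS")
  out
}

#' Bin the baroreflex table by 1-mmHg of diastolic pressure
#'
#' Bins are `[k, k + 1)` mmHg for integer `k`; empty bins are omitted.
#'
#' @param table Output of [build_baro_table()].
#' @return A tibble: `bin_center` (mmHg), `n`, `p_occurrence` (%),
#'   `mean_area` (%).
#' @export
bin_by_dbp <- function(table) {
  stopifnot(nrow(table) > 0)
  table |>
    dplyr::mutate(bin = floor(.data$dbp)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      p_occurrence = 100 * mean(.data$occurred_next),
      mean_area = mean(.data$area_next),
      .groups = "drop") |>
    dplyr::mutate(bin_center = .data$bin + 0.5) |>
    dplyr::select("bin_center", "n", "p_occurrence", "mean_area") |>
    dplyr::arrange(.data$bin_center)
}

#' Weighted-regression slope of the sympathetic baroreflex
#'
#' Weighted least squares of burst-occurrence probability (or mean burst
#' area) on diastolic-pressure bin centre, weights equal to the bin
#' counts. The slope is the spontaneous sympathetic baroreflex
#' sensitivity (sBRS). A fit needs at least `min_bins` bins spanning at
#' least `min_range_mmhg`; otherwise the result is flagged unavailable
#' (not an error), mirroring per-subject missingness.
#'
#' @param bins Binned table from [bin_by_dbp()] (columns `bin_center`,
#'   `n`, and the response for `response`).
#' @param response `"occurrence"` (uses `p_occurrence`, slope in
#'   % bursts/mmHg) or `"area"` (uses `mean_area`, slope in %/mmHg).
#' @param min_bins,min_range_mmhg Validity thresholds for the fit.
#' @return An object of class `sbrs_fit`: `slope`, `intercept`,
#'   `weighted_r`, `n_bins`, `range_mmhg`, `n_beats`, `available`,
#'   `response`, `bins`.
#' @export
sbrs_slope <- function(bins, response = c("occurrence", "area"),
                       min_bins = 3, min_range_mmhg = 3) {
  response <- match.arg(response)
  ycol <- if (response == "occurrence") "p_occurrence" else "mean_area"
  x <- bins$bin_center
  y <- bins[[ycol]]
  w <- bins$n
  range_mmhg <- if (length(x)) diff(range(x)) + 1 else 0
  out <- list(slope = NA_real_, intercept = NA_real_,
              weighted_r = NA_real_, n_bins = length(x),
              range_mmhg = range_mmhg, n_beats = sum(w),
              available = FALSE, response = response, bins = bins)
  if (length(x) >= min_bins && range_mmhg >= min_range_mmhg) {
    fit <- stats::lm(y ~ x, weights = w)
    mx <- stats::weighted.mean(x, w)
    my <- stats::weighted.mean(y, w)
    sxy <- sum(w * (x - mx) * (y - my))
    sxx <- sum(w * (x - mx)^2)
    syy <- sum(w * (y - my)^2)
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    out$weighted_r <- if (sxx > 0 && syy > 0) sxy / sqrt(sxx * syy) else NA_real_
    out$available <- is.finite(out$slope)
  }
  structure(out, class = "sbrs_fit")
}

#' @export
print.sbrs_fit <- function(x, ...) {
  if (x$available) {
    cat(sprintf("<sbrs_fit> %s: slope %.3f per mmHg (weighted r %.3f, %d bins over %g mmHg, %d beats)\n",
                x$response, x$slope, x$weighted_r, x$n_bins, x$range_mmhg,
                x$n_beats))
  } else {
    cat(sprintf("<sbrs_fit> %s: unavailable (%d bins over %g mmHg)\n",
                x$response, x$n_bins, x$range_mmhg))
  }
  invisible(x)
}

#' Spontaneous sympathetic baroreflex sensitivity, end to end
#'
#' Builds the per-beat table, bins by diastolic pressure and fits both
#' weighted-regression slopes (burst occurrence and burst area).
#'
#' @inheritParams build_baro_table
#' @param min_bins,min_range_mmhg Passed to [sbrs_slope()].
#' @return A list of class `sbrs_result` with `occurrence` and `area`
#'   (`sbrs_fit` objects), `bins`, and `table`.
#' @export
sbrs <- function(beats, bursts, neurogram, min_bins = 3,
                 min_range_mmhg = 3) {
  table <- build_baro_table(beats, bursts, neurogram)
  bins <- bin_by_dbp(table)
  structure(list(
    occurrence = sbrs_slope(bins, "occurrence", min_bins, min_range_mmhg),
    area = sbrs_slope(bins, "area", min_bins, min_range_mmhg),
    bins = bins, table = table
  ), class = "sbrs_result")
}

#' @export
print.sbrs_result <- function(x, ...) {
  print(x$occurrence)
  print(x$area)
  invisible(x)
}
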