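#' Respiratory sinus arrhythmia per breath
#'
#' RSA for each respiratory cycle is the maximum absolute change in
#' beat-to-beat heart rate between adjacent end-expiration points
#' (respiratory troughs): the max minus min of `hr` over beats whose R
#' time falls in `[t_trough_k, t_trough_{k+1})`. Breaths holding fewer
#' than two beats have undefined RSA and are excluded from the mean.
#'
#' @param beats Beat table from [beat_hemodynamics()].
#' @param cycles Breath table from [detect_resp_cycles()].
#' @return A tibble: `breath`, `n_beats`, `rsa` (beats/min).
#' @export
rsa_per_breath <- function(beats, cycles) {
  per_breath_range(beats$r_time, beats$hr, cycles, extend_s = 0,
                   value_name = "rsa")
}

#' Traube-Hering wave amplitude per breath
#'
#' The maximum absolute change in beat-to-beat mean arterial pressure
#' between one end-expiration point and the next end-expiration point
#' plus 1 s: max minus min of `map` over beats in
#' `[t_trough_k, t_trough_{k+1} + 1)`.
#'
#' @inheritParams rsa_per_breath
#' @param extend_s Window extension past the next end-expiration point, s.
#' @return A tibble: `breath`, `n_beats`, `th` (mmHg).
#' @export
th_per_breath <- function(beats, cycles, extend_s = 1) {
  per_breath_range(beats$r_time, beats$map, cycles, extend_s = extend_s,
                   value_name = "th")
}

per_breath_range <- function(times, values, cycles, extend_s, value_name) {
  out <- purrr::pmap(cycles[, c("breath", "t_trough", "t_trough_next")],
                     function(breath, t_trough, t_trough_next) {
                       v <- values[times >= t_trough &
                                     times < t_trough_next + extend_s]
                       tibble::tibble(breath = breath,
                                      n_beats = length(v),
                                      value = if (length(v) >= 2)
                                        max(v) - min(v) else NA_real_)
                     }) |>
    dplyr::bind_rows()
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Respiratory-modulated MSNA per breath
#'
#' The modulus (integral) of the original, unshifted integrated neurogram
#' over 1.5 times the duration of inspiration, from the start of
#' inspiration. Computed on the raw voltage trace by default (units
#' V.s); pass a normalized `neurogram` object to integrate in % units
#' instead. Breaths whose integration window runs past the record end are
#' dropped.
#'
#' @param msna Raw MSNA vector (V) or an unshifted `neurogram` object.
#' @param cycles Breath table from [detect_resp_cycles()].
#' @param fs Sample rate, required when `msna` is a raw vector.
#' @return A tibble: `breath`, `msna_resp` (V.s, or %.s for a normalized
#'   input).
#' @export
resp_modulated_msna <- function(msna, cycles, fs = NULL) {
  if (inherits(msna, "neurogram")) {
    if (msna$shift_applied != 0) {
      stop("resp_modulated_msna requires the unshifted neurogram")
    }
    x <- msna$samples
    fs <- msna$fs
    t0 <- msna$start_time
  } else {
    if (is.null(fs)) stop("`fs` must be supplied with a raw vector")
    x <- as.numeric(msna)
    t0 <- 0
  }
  n <- length(x)
  purrr::pmap(cycles[, c("breath", "t_trough", "insp_dur")],
              function(breath, t_trough, insp_dur) {
                a <- t_trough
                b <- t_trough + 1.5 * insp_dur
                i0 <- max(1L, floor((a - t0) * fs) + 1L)
                i1 <- floor((b - t0) * fs)
                if (i1 > n) {
                  return(tibble::tibble(breath = breath,
                                        msna_resp = NA_real_))
                }
                tibble::tibble(breath = breath,
                               msna_resp = sum(x[i0:i1], na.rm = TRUE) / fs)
              }) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$msna_resp))
}

#' Per-breath hemodynamics table (RSA, TH, respiratory-modulated MSNA)
#'
#' Joins the three per-breath measures on breath index.
#'
#' @inheritParams rsa_per_breath
#' @inheritParams resp_modulated_msna
#' @return A tibble: `breath`, `rsa`, `th`, `msna_resp`.
#' @export
breath_hemodynamics <- function(beats, cycles, msna, fs = NULL) {
  rsa <- rsa_per_breath(beats, cycles)
  th <- th_per_breath(beats, cycles)
  mr <- resp_modulated_msna(msna, cycles, fs = fs)
  rsa |>
    dplyr::select("breath", "rsa") |>
    dplyr::left_join(dplyr::select(th, "breath", "th"), by = "breath") |>
    dplyr::left_join(mr, by = "breath")
}

#' Lagged correlation of respiratory-modulated MSNA with Traube-Hering waves
#'
#' Per-subject correlation between the per-breath MSNA measure and TH
#' amplitude of the same breath (lag 0), the following breath (+1) and
#' the previous breath (-1). A subject is flagged "significant positive"
#' at a lag when p < 0.05 and the coefficient is positive.
#'
#' @param msna_resp Per-breath MSNA values (ordered by breath).
#' @param th Per-breath TH amplitudes (same breaths).
#' @param lags Integer lags to evaluate.
#' @param method `"pearson"` (default; per-participant product-moment
#'   coefficients) or `"spearman"`.
#' @return A tibble: `lag`, `r`, `p_value`, `n`, `significant_positive`.
#' @export
lagged_coupling <- function(msna_resp, th, lags = c(-1L, 0L, 1L),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(msna_resp) == length(th))
  n <- length(msna_resp)
  purrr::map(lags, function(L) {
    ks <- seq(max(1, 1 - L), min(n, n - L))
    x <- msna_resp[ks]
    y <- th[ks + L]
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(lag = L, r = NA_real_, p_value = NA_real_,
                            n = length(x), significant_positive = NA))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    tibble::tibble(lag = L, r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x),
                   significant_positive = ct$p.value < 0.05 &&
                     unname(ct$estimate) > 0)
  }) |>
    dplyr::bind_rows()
}
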