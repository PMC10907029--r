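#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.sbrs_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    slope = x$slope,
    intercept = x$intercept,
    weighted_r = x$weighted_r,
    n_bins = x$n_bins,
    range_mmhg = x$range_mmhg,
    n_beats = x$n_beats,
    available = x$available
  )
}

#' @exportS3Method generics::tidy
tidy.sbrs_result <- function(x, ...) {
  dplyr::bind_rows(tidy(x$occurrence), tidy(x$area))
}

#' @exportS3Method generics::glance
glance.sbrs_result <- function(x, ...) {
  tibble::tibble(
    slope_occurrence = x$occurrence$slope,
    slope_area = x$area$slope,
    weighted_r_occurrence = x$occurrence$weighted_r,
    weighted_r_area = x$area$weighted_r,
    n_bins = x$occurrence$n_bins,
    range_mmhg = x$occurrence$range_mmhg,
    n_beats = x$occurrence$n_beats
  )
}

#' @exportS3Method generics::tidy
tidy.phase_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.phase_anova <- function(x, ...) {
  ia <- x[x$effect == "phase:group", ]
  tibble::tibble(
    interaction_F = ia$statistic,
    interaction_p = ia$p_value,
    interaction_partial_eta_sq = ia$partial_eta_sq
  )
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p_value = x$p_value
  )
}

#' @exportS3Method generics::tidy
tidy.proportion_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic, df = x$df,
                 p_value = x$p_value)
}

#' @exportS3Method generics::tidy
tidy.subject_analysis <- function(x, ...) {
  x$summary
}
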