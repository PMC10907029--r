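#' Write a recording (and optional ground truth) to CSV + JSON sidecar
#'
#' The sample table goes to `<prefix>.csv` (columns `t`, `ecg`, `pressure`,
#' `respiration`, `msna`) and the sample rate, parameters and any ground
#' truth to `<prefix>.json`.
#'
#' @param record An [msna_record()].
#' @param prefix Output path prefix (no extension).
#' @param truth Optional ground-truth list from [generate_subject()].
#' @return Invisibly, the two file paths.
#' @export
write_record <- function(record, prefix, truth = NULL) {
  record <- as_record(record)
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  readr::write_csv(record$data, csv)
  side <- list(fs = record$fs, start_time = record$start_time)
  if (!is.null(truth)) {
    side$params <- unclass(truth$params)
    side$r_times <- truth$r_times
    side$beats <- truth$beats
    side$resp_landmarks <- truth$resp_landmarks
    side$bursts <- truth$bursts
  }
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(c(csv = csv, json = json))
}

#' Read a recording written by [write_record()]
#'
#' @param prefix Path prefix used when writing.
#' @return A list with `record` (an [msna_record()]) and `truth` (`NULL`
#'   when the sidecar holds no ground truth).
#' @export
read_record <- function(prefix) {
  data <- readr::read_csv(paste0(prefix, ".csv"),
                          show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  record <- msna_record(data, fs = side$fs,
                        start_time = side$start_time %||% 0)
  truth <- NULL
  if (!is.null(side$params)) {
    truth <- list(
      params = do.call(subject_params, side$params),
      r_times = side$r_times,
      beats = tibble::as_tibble(side$beats),
      resp_landmarks = tibble::as_tibble(side$resp_landmarks),
      bursts = tibble::as_tibble(side$bursts)
    )
  }
  list(record = record, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
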