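#' Classify physical-activity status from daily MVPA
#'
#' Children meeting the recommendation of at least 60 minutes of
#' moderate-to-vigorous physical activity (MVPA) per day are classified as
#' active; below 60 min/day as inactive. The boundary is inclusive: exactly
#' 60 min/day is active.
#'
#' @param mvpa_min_day Daily MVPA in minutes (nonnegative; vectorized).
#' @param threshold_min Recommendation threshold in minutes per day.
#' @return Logical vector: `TRUE` for active; `NA` propagates.
#' @export
classify_activity <- function(mvpa_min_day, threshold_min = 60) {
  if (any(mvpa_min_day < 0, na.rm = TRUE)) {
    stop("mvpa_min_day must be nonnegative", call. = FALSE)
  }
  mvpa_min_day >= threshold_min
}
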