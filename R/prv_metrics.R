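#' Mean heart rate from an interval series
#'
#' Default convention: `HR = 60000 / mean(IBI in ms)` — one minute of
#' measurement time over the mean inter-beat interval, the dimensionally
#' coherent reading that reproduces BPM-scale cohort values. The
#' alternative convention (mean of instantaneous per-beat rates) is
#' available via `method = "instantaneous"`.
#'
#' @param ibi an [ibi_series()] (or numeric vector of intervals, ms).
#' @param method `"mean_ibi"` (default) or `"instantaneous"`.
#' @return mean heart rate in bpm.
#' @export
mean_hr <- function(ibi, method = c("mean_ibi", "instantaneous")) {
  method <- match.arg(method)
  x <- interval_vector(ibi, min_n = 1L)
  switch(method,
         mean_ibi = 60000 / mean(x),
         instantaneous = mean(60000 / x))
}

#' SDNN: standard deviation of normal-to-normal intervals
#'
#' Sample standard deviation over all `N` intervals (denominator
#' `N - 1`).
#'
#' @param ibi an [ibi_series()] (or numeric vector, ms); >= 2 intervals.
#' @return SDNN in ms.
#' @export
sdnn <- function(ibi) {
  x <- interval_vector(ibi, min_n = 2L)
  stats::sd(x)
}

#' RMSSD: root mean square of successive differences
#'
#' Default estimator: root mean square over all `N - 1` successive
#' differences (denominator = number of differences). The `literal`
#' variant divides by `N - 2` instead, preserving a printed-form variant
#' encountered in the field; it requires at least 3 intervals.
#'
#' @param ibi an [ibi_series()] (or numeric vector, ms).
#' @param literal if `TRUE`, divide by `N - 2` instead of `N - 1`.
#' @return RMSSD in ms.
#' @export
rmssd <- function(ibi, literal = FALSE) {
  x <- interval_vector(ibi, min_n = if (literal) 3L else 2L)
  d <- diff(x)
  denom <- if (literal) length(x) - 2L else length(d)
  sqrt(sum(d^2) / denom)
}

#' Data loss of a recording
#'
#' Percentage of expected sample slots that are missing:
#' `100 * missing / expected`.
#'
#' @param signal a [sampled_signal()].
#' @return data loss in percent.
#' @export
data_loss <- function(signal) {
  stop_if_not_signal(signal)
  n <- length(signal$values)
  if (n < 1L) stop("signal must contain at least one expected slot")
  100 * sum(signal$missing_mask) / n
}

#' Summarize one recording
#'
#' Aggregates the time-domain indicators and the data-loss statistic for
#' a single recording into a `prv_summary`.
#'
#' @param ibi detected (or truth) [ibi_series()]; >= 2 intervals.
#' @param signal the recorded [sampled_signal()] (for duration and data
#'   loss); optional — without it duration is taken from the intervals
#'   and data loss is `NA`.
#' @param hr_method heart-rate convention, see [mean_hr()].
#' @return an object of class `prv_summary` with fields `mean_hr`,
#'   `mean_ibi`, `sdnn`, `rmssd`, `n_events`, `duration`, `data_loss`.
#' @export
prv_summarize <- function(ibi, signal = NULL,
                          hr_method = c("mean_ibi", "instantaneous")) {
  hr_method <- match.arg(hr_method)
  x <- interval_vector(ibi, min_n = 2L)
  duration <- if (!is.null(signal)) {
    stop_if_not_signal(signal)
    length(signal$values) / signal$sampling_rate
  } else sum(x) / 1000
  structure(
    list(mean_hr = mean_hr(ibi, method = hr_method),
         mean_ibi = mean(x),
         sdnn = sdnn(ibi),
         rmssd = rmssd(ibi),
         n_events = length(x) + 1L,
         duration = duration,
         data_loss = if (!is.null(signal)) data_loss(signal) else NA_real_),
    class = "prv_summary")
}

#' @export
print.prv_summary <- function(x, ...) {
  cat(sprintf(paste0("<prv_summary> HR %.2f bpm | IBI %.1f ms | SDNN %.2f ms | ",
                     "RMSSD %.2f ms | %d events over %.1f s | loss %.2f%%\n"),
              x$mean_hr, x$mean_ibi, x$sdnn, x$rmssd, x$n_events,
              x$duration, x$data_loss))
  invisible(x)
}

#' Serialize a recording summary as JSON
#'
#' @param x a `prv_summary`.
#' @param path output file; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to file.
#' @export
write_prv_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "prv_summary"))
  obj <- list(schema_version = 1L,
              mean_hr_bpm = x$mean_hr, mean_ibi_ms = x$mean_ibi,
              sdnn_ms = x$sdnn, rmssd_ms = x$rmssd,
              n_events = x$n_events, duration_s = x$duration,
              data_loss_pct = x$data_loss)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}

#' One-row data frame of a recording summary (for cohort assembly)
#'
#' @param x a `prv_summary`.
#' @return a one-row `data.frame`.
#' @export
as.data.frame.prv_summary <- function(x, ...) {
  data.frame(mean_hr_bpm = x$mean_hr, mean_ibi_ms = x$mean_ibi,
             sdnn_ms = x$sdnn, rmssd_ms = x$rmssd, n_events = x$n_events,
             duration_s = x$duration, data_loss_pct = x$data_loss)
}

# Coerce an ibi_series or numeric vector to a validated interval vector.
interval_vector <- function(ibi, min_n = 1L) {
  x <- if (inherits(ibi, "ibi_series")) ibi$intervals else as.numeric(ibi)
  if (length(x) < min_n)
    stop(sprintf("need at least %d interval(s), got %d", min_n, length(x)))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intervals must be finite and > 0")
  x
}
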