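#' Uniformly sampled signal container
#'
#' Holds a uniformly sampled waveform (typically a raw or processed PPG
#' trace) together with its nominal sampling rate and a per-slot missing
#' mask. Missing slots keep their position on the sample grid (value `NA`,
#' mask `TRUE`) so that data-loss accounting and beat timing are unaffected
#' by later gap repair.
#'
#' @param values numeric vector of sample amplitudes (arbitrary units);
#'   `NA` marks a missing slot.
#' @param sampling_rate sampling frequency in Hz; must be positive.
#' @param start_time time of the first sample slot, in seconds.
#' @param missing_mask logical vector flagging missing slots; defaults to
#'   `is.na(values)`. Must have the same length as `values`.
#' @return an object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, sampling_rate, start_time = 0,
                           missing_mask = NULL) {
  values <- as.numeric(values)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.logical(missing_mask)
  if (length(missing_mask) != length(values))
    stop("`missing_mask` length must equal `values` length")
  # masked slots may carry either the NA sentinel or repaired values
  # (fill_missing keeps the mask for data-loss accounting)
  if (anyNA(values[!missing_mask]))
    stop("unmasked slots must not be NA")
  structure(
    list(values = values, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time), missing_mask = missing_mask),
    class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz (%.2f s), %d missing (%.2f%%)\n",
              length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate,
              sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Sample time stamps of a signal
#'
#' @param x a [sampled_signal()].
#' @return numeric vector of slot times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$start_time + (seq_along(x$values) - 1L) / x$sampling_rate
}

# Clone a signal with new values, keeping rate/start/mask metadata.
signal_with_values <- function(x, values, missing_mask = x$missing_mask) {
  sampled_signal(values, x$sampling_rate, x$start_time,
                 missing_mask = missing_mask)
}

#' Inter-beat interval series
#'
#' Ordered beat-to-beat intervals in milliseconds with cumulative event
#' times. The convention is: `N` intervals, `event_times` of length `N`
#' giving the onset (start) of each interval in seconds; the series origin
#' records whether the intervals are simulated truth, detector output, or
#' read from an interval file.
#'
#' @param intervals numeric vector of intervals in ms, all positive.
#' @param event_times optional numeric vector of interval onsets in
#'   seconds, strictly increasing, same length as `intervals`. Defaults to
#'   the cumulative sum of the intervals starting at 0.
#' @param origin one of `"truth"`, `"detected"`, `"file"`.
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(intervals, event_times = NULL,
                       origin = c("truth", "detected", "file")) {
  origin <- match.arg(origin)
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("`intervals` must be non-empty")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all intervals must be finite and > 0")
  if (is.null(event_times)) {
    event_times <- cumsum(c(0, intervals[-length(intervals)])) / 1000
  }
  event_times <- as.numeric(event_times)
  if (length(event_times) != length(intervals))
    stop("`event_times` must have one onset per interval")
  if (any(diff(event_times) <= 0))
    stop("`event_times` must be strictly increasing")
  structure(list(intervals = intervals, event_times = event_times,
                 origin = origin),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals (%s), mean %.1f ms, range [%.0f, %.0f] ms\n",
              length(x$intervals), x$origin, mean(x$intervals),
              min(x$intervals), max(x$intervals)))
  invisible(x)
}

#' @export
length.ibi_series <- function(x) length(x$intervals)
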