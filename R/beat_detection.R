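#' Parameters of the windowed APG beat detector
#'
#' The detector marks cardiac events on the APG with a windowed decision
#' rule. Candidates are strict local maxima; a candidate at sample `k`
#' becomes an event when its local-peak statistic
#' `dy(k) = y(k) - ref(k)` exceeds the threshold `theta` of the data
#' window (default 20 s) it falls in. `ref(k)` is built from the samples
#' `comparison_halfwidth` seconds away (default 0.25 s, i.e. a
#' comparison span of half the sampling frequency in samples), so `dy`
#' measures the candidate's prominence over its immediate cardiac-cycle
#' neighborhood: the secondary positive APG lobes of a beat sit next to
#' the dominant one and receive a negative `dy`. All other samples are
#' set to zero. A refractory rule finally keeps the larger of any two
#' events closer than `refractory` ms.
#'
#' @param window_length data window length in seconds (default 20); sets
#'   the span over which the adaptive threshold is derived.
#' @param threshold_policy `"quantile"` (default): `theta` is the
#'   `theta`-quantile of the window's positive APG amplitudes, making the
#'   rule amplitude-scale invariant; `"fixed"`: `theta` is an absolute
#'   amplitude.
#' @param theta quantile fraction in (0,1) (quantile policy, default 0.6)
#'   or absolute threshold (fixed policy).
#' @param refractory minimum inter-event gap in ms (default 250, a
#'   240 bpm ceiling guarding against double detection on the two APG
#'   lobes of one beat).
#' @param comparison_halfwidth offset of the comparison samples in
#'   seconds (default 0.25 s = half of a half-sampling-frequency span).
#' @param reference `"both_sides"` (default): the candidate must exceed
#'   both flanking samples by `theta`, i.e. `ref(k)` is the larger of the
#'   samples at `k - h` and `k + h` (clipped to the window) — the reading
#'   of the two-sided comparison that is robust to the deep negative APG
#'   valley; `"mean"`: `ref(k)` is the mean of the two flanking samples;
#'   `"one_sided"`: `ref(k)` is the single sample at `k + h`.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(window_length = 20,
                            threshold_policy = c("quantile", "fixed"),
                            theta = 0.6, refractory = 250,
                            comparison_halfwidth = 0.25,
                            reference = c("both_sides", "mean",
                                          "one_sided")) {
  threshold_policy <- match.arg(threshold_policy)
  reference <- match.arg(reference)
  if (window_length <= 0) stop("`window_length` must be > 0")
  if (threshold_policy == "quantile" && (theta <= 0 || theta >= 1))
    stop("quantile `theta` must lie in (0, 1)")
  if (refractory < 0) stop("`refractory` must be >= 0")
  if (comparison_halfwidth <= 0)
    stop("`comparison_halfwidth` must be > 0")
  structure(list(window_length = window_length,
                 threshold_policy = threshold_policy, theta = theta,
                 refractory = refractory,
                 comparison_halfwidth = comparison_halfwidth,
                 reference = reference),
            class = "detector_params")
}

# Strict local maxima; on a plateau the first sample of the flat run wins.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] &
    r$values[mid] > r$values[mid + 1L]
  starts[mid][is_max]
}

#' Detect cardiac events on the APG
#'
#' Implements the windowed decision rule described in
#' [detector_params()]. Candidates are strict local maxima of the whole
#' APG; each candidate is judged against the threshold of the window it
#' falls in. An all-flat window contributes no events (not an error).
#'
#' @param apg the APG as a [sampled_signal()] (output of
#'   [preprocess_ppg()] / [second_derivative()]).
#' @param params a [detector_params()].
#' @return an object of class `event_array`: list with `event_indices`
#'   (1-based sample positions, strictly increasing), `z` (logical per
#'   sample), and `sampling_rate`.
#' @export
detect_events <- function(apg, params = detector_params()) {
  stop_if_not_signal(apg)
  stopifnot(inherits(params, "detector_params"))
  fs <- apg$sampling_rate
  y <- apg$values
  if (anyNA(y))
    stop("APG has missing samples; preprocess with fill_missing() first")
  n <- length(y)
  wlen <- as.integer(round(params$window_length * fs))
  if (n < wlen)
    stop(sprintf("signal (%d samples) is shorter than one %g-s window (%d samples)",
                 n, params$window_length, wlen))
  half <- max(1L, as.integer(round(params$comparison_halfwidth * fs)))

  cand <- local_maxima(y)
  keep <- logical(length(cand))
  if (length(cand)) {
    win_id <- (cand - 1L) %/% wlen
    for (w in unique(win_id)) {
      w0 <- w * wlen + 1L
      w1 <- min(n, w0 + wlen - 1L)
      seg <- y[w0:w1]
      theta <- if (params$threshold_policy == "fixed") {
        params$theta
      } else {
        pos <- seg[seg > 0]
        if (!length(pos)) next  # flat/non-positive window: no events
        stats::quantile(pos, params$theta, names = FALSE, type = 7)
      }
      idx <- cand[win_id == w]
      # flanks clip to the record, not the window: the window only sets
      # the threshold, otherwise peaks at window seams lose their context
      lo <- pmax(1L, idx - half)
      hi <- pmin(n, idx + half)
      ref <- switch(params$reference,
                    both_sides = pmax(y[lo], y[hi]),
                    mean = (y[lo] + y[hi]) / 2,
                    one_sided = y[hi])
      keep[win_id == w] <- (y[idx] - ref) > theta
    }
  }
  ev <- cand[keep]

  # refractory suppression: greedy by amplitude, earlier index on ties
  gap <- as.integer(round(params$refractory / 1000 * fs))
  if (gap > 0L && length(ev) > 1L) {
    ord <- ev[order(-y[ev], ev)]
    accepted <- integer(0)
    for (i in ord) {
      if (!length(accepted) || all(abs(accepted - i) >= gap))
        accepted <- c(accepted, i)
    }
    ev <- sort(accepted)
  }

  z <- logical(n)
  z[ev] <- TRUE
  structure(list(event_indices = as.integer(ev), z = z, sampling_rate = fs),
            class = "event_array")
}

#' @export
print.event_array <- function(x, ...) {
  cat(sprintf("<event_array> %d events over %d samples @ %g Hz\n",
              length(x$event_indices), length(x$z), x$sampling_rate))
  invisible(x)
}

#' Peak-to-peak intervals from detected events
#'
#' Converts detected event sample indices to intervals:
#' `PP_i = (index_{i+1} - index_i) / fs * 1000` ms. `N` events yield
#' `N - 1` intervals.
#'
#' @param events an `event_array` from [detect_events()], or a bare
#'   integer vector of sample indices.
#' @param sampling_rate sampling rate in Hz (taken from the event array
#'   when available).
#' @return an [ibi_series()] with `origin = "detected"`.
#' @export
pp_intervals <- function(events, sampling_rate = NULL) {
  idx <- if (inherits(events, "event_array")) events$event_indices else
    as.integer(events)
  if (is.null(sampling_rate)) {
    if (!inherits(events, "event_array"))
      stop("`sampling_rate` is required for bare index vectors")
    sampling_rate <- events$sampling_rate
  }
  if (length(idx) < 2L) stop("insufficient events (need >= 2)")
  pp <- diff(idx) / sampling_rate * 1000
  onsets <- (idx[-length(idx)] - 1L) / sampling_rate
  ibi_series(pp, event_times = onsets, origin = "detected")
}

#' Remove implausible intervals
#'
#' Rejects intervals outside an absolute range and intervals deviating
#' from a centered running median (window 11) by more than a relative
#' band. Setting `median_band = 0` disables the running-median rule.
#'
#' @param ibi an [ibi_series()].
#' @param min_ms,max_ms absolute plausibility range (defaults 300/2000).
#' @param median_band maximal allowed relative deviation from the running
#'   median (default 0.3); 0 disables.
#' @return list with `ibi` (surviving [ibi_series()]; `NULL` if nothing
#'   survives) and `n_rejected`.
#' @export
clean_intervals <- function(ibi, min_ms = 300, max_ms = 2000,
                            median_band = 0.3) {
  stop_if_not_ibi(ibi)
  x <- ibi$intervals
  ok <- x >= min_ms & x <= max_ms
  if (median_band > 0 && length(x) >= 2L) {
    k <- min(11L, length(x) - (1L - length(x) %% 2L))  # largest odd <= n
    med <- if (k >= 3L) stats::runmed(x, k, endrule = "median")
           else rep(stats::median(x), length(x))
    ok <- ok & abs(x - med) <= median_band * med
  }
  n_rej <- sum(!ok)
  out <- if (any(ok))
    ibi_series(x[ok], event_times = ibi$event_times[ok],
               origin = ibi$origin)
  else NULL
  list(ibi = out, n_rejected = n_rej)
}
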