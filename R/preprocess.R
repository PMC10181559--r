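#' Filter specification for the PPG conditioning chain
#'
#' Bundles the parameters of the four-stage conditioning chain applied to
#' raw PPG before beat detection: moving average, airPLS baseline
#' correction, low-pass IIR filtering, second derivative. Defaults follow
#' the reference pipeline for a 40 Hz sensor: a 5-sample (125 ms) moving
#' average, airPLS with `lambda = 1e5`, and a sixth-order Butterworth
#' low-pass at 18 Hz.
#'
#' @param ma_window moving-average window in samples; odd, >= 1.
#' @param airpls_lambda smoothness weight of the baseline fit, > 0.
#' @param airpls_max_iter maximum reweighting iterations, >= 1.
#' @param lowpass_cutoff low-pass cutoff in Hz (checked against Nyquist at
#'   apply time).
#' @param lowpass_order filter order.
#' @param mode `"offline"` (forward-backward passes, zero net phase) or
#'   `"streaming"` (single causal pass; the group delay estimate is
#'   attached to the output).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(ma_window = 5, airpls_lambda = 1e5,
                        airpls_max_iter = 15, lowpass_cutoff = 18,
                        lowpass_order = 6,
                        mode = c("offline", "streaming")) {
  mode <- match.arg(mode)
  ma_window <- as.integer(ma_window)
  if (ma_window < 1L || ma_window %% 2L == 0L)
    stop("`ma_window` must be an odd integer >= 1")
  if (airpls_lambda <= 0) stop("`airpls_lambda` must be > 0")
  if (airpls_max_iter < 1) stop("`airpls_max_iter` must be >= 1")
  if (lowpass_cutoff <= 0) stop("`lowpass_cutoff` must be > 0")
  if (lowpass_order < 1) stop("`lowpass_order` must be >= 1")
  structure(list(ma_window = ma_window, airpls_lambda = airpls_lambda,
                 airpls_max_iter = as.integer(airpls_max_iter),
                 lowpass_cutoff = lowpass_cutoff,
                 lowpass_order = as.integer(lowpass_order), mode = mode),
            class = "filter_spec")
}

#' Centered moving average with shrinking edges
#'
#' Arithmetic mean over a centered odd window; near the edges the window
#' shrinks to the available samples, so output length equals input length.
#' Missing slots must be repaired first (see [fill_missing()]).
#'
#' @param signal a [sampled_signal()] (or bare numeric vector).
#' @param window odd window length in samples.
#' @return filtered signal of the same class and length.
#' @export
moving_average <- function(signal, window) {
  x <- if (inherits(signal, "sampled_signal")) signal$values else signal
  window <- as.integer(window)
  if (window %% 2L == 0L)
    stop("`window` must be odd (centered window has no unambiguous center otherwise)")
  if (window < 1L || window > length(x))
    stop("`window` must lie in [1, signal length]")
  if (anyNA(x))
    stop("signal has missing samples; call fill_missing() first")
  h <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(signal, "sampled_signal"))
    signal_with_values(signal, out) else out
}

# airPLS baseline: adaptive iteratively reweighted penalized least
# squares (Whittaker smoother with a second-difference penalty; weights
# of points above the running baseline are shrunk each iteration).
airpls_baseline <- function(y, lambda = 1e5, max_iter = 15) {
  m <- length(y)
  if (m < 3L) stop("signal must have length >= 3")
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  # convergence scale centered so the stop rule (and hence the output)
  # is invariant to a constant offset of the input
  abs_y <- sum(abs(y - mean(y)))
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    d <- y - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    # converged: points below the baseline carry <0.1% of total signal mass
    if (dssn < 0.001 * abs_y || !any(neg)) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
    w[1L] <- exp(it * max(abs(d[neg])) / dssn)
    w[m] <- w[1L]
  }
  z
}

#' Baseline correction by airPLS
#'
#' Estimates a smooth baseline by adaptive iteratively reweighted
#' penalized least squares and returns the signal minus the baseline.
#' Drift (e.g. respiration- or motion-induced wander that survived the
#' moving average) is absorbed into the baseline; the pulsatile component
#' is preserved.
#'
#' @param signal a [sampled_signal()] (or numeric vector), length >= 3,
#'   no missing samples.
#' @param lambda smoothness weight (> 0); larger = stiffer baseline.
#' @param max_iter maximum reweighting iterations.
#' @return baseline-corrected signal, same class and length.
#' @export
baseline_correct_airpls <- function(signal, lambda = 1e5, max_iter = 15) {
  if (lambda <= 0) stop("`lambda` must be > 0")
  x <- if (inherits(signal, "sampled_signal")) signal$values else signal
  if (anyNA(x))
    stop("signal has missing samples; call fill_missing() first")
  out <- x - airpls_baseline(x, lambda = lambda, max_iter = max_iter)
  if (inherits(signal, "sampled_signal"))
    signal_with_values(signal, out) else out
}

# Butterworth low-pass coefficients via bilinear transform.
# Returns list(b, a) with a[1] = 1 and unit DC gain.
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 cutoff, fs / 2))
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half plane
  p <- exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))
  warped <- 2 * fs * tan(pi * cutoff / fs)
  p <- warped * p
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)              # bilinear-transformed poles
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))  # zeros at z = -1
  b <- b * sum(a) / sum(b)                  # normalize to unit DC gain
  list(b = b, a = a)
}

# Causal direct-form IIR filter with zero initial state.
iir_filter <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

# Forward-backward filtering with odd-reflection edge padding (zero net
# phase, squared magnitude response).
iir_filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, 6L * (max(length(a), length(b)) - 1L))
  if (padlen > 0L) {
    pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  if (padlen > 0L) y[(padlen + 1L):(padlen + n)] else y
}

# Analytic magnitude response of the digital (bilinear) Butterworth
# low-pass at frequency f, for one causal pass.
butter_response <- function(order, cutoff, fs, f) {
  ratio <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / sqrt(1 + ratio^(2 * order))
}

#' Low-pass IIR (Butterworth) filtering
#'
#' Applies the spec's sixth-order Butterworth low-pass. In `offline` mode
#' the filter runs forward and backward (zero net phase; the effective
#' magnitude response is squared). In `streaming` mode a single causal
#' pass is applied and the estimated group delay (samples, evaluated at
#' 10% of the cutoff) is attached as attribute `group_delay_samples`.
#'
#' @param signal a [sampled_signal()].
#' @param spec a [filter_spec()].
#' @return filtered [sampled_signal()].
#' @export
lowpass_iir <- function(signal, spec = filter_spec()) {
  stop_if_not_signal(signal)
  stopifnot(inherits(spec, "filter_spec"))
  fs <- signal$sampling_rate
  if (spec$lowpass_cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 spec$lowpass_cutoff, fs / 2))
  x <- signal$values
  if (anyNA(x))
    stop("signal has missing samples; call fill_missing() first")
  coef <- butter_lowpass(spec$lowpass_order, spec$lowpass_cutoff, fs)
  if (spec$mode == "offline") {
    out <- signal_with_values(signal, iir_filtfilt(coef$b, coef$a, x))
  } else {
    y <- iir_filter(coef$b, coef$a, x)
    # group delay ~ -dphi/domega from the response at a low passband freq
    f0 <- spec$lowpass_cutoff / 10
    w <- 2 * pi * f0 / fs
    h <- function(w) {
      z <- exp(-1i * w * (seq_along(coef$b) - 1L))
      sum(coef$b * z) / sum(coef$a * exp(-1i * w * (seq_along(coef$a) - 1L)))
    }
    dw <- 1e-4
    gd <- -(Arg(h(w + dw)) - Arg(h(w - dw))) / (2 * dw)
    out <- signal_with_values(signal, y)
    attr(out, "group_delay_samples") <- gd
  }
  out
}

#' Second derivative (acceleration plethysmogram)
#'
#' Central second difference scaled by the squared sampling interval;
#' the two endpoints reuse the one-sided second difference of their
#' nearest interior neighbor, so output length equals input length.
#' Applied to a conditioned PPG this yields the APG, whose dominant
#' positive peak per cardiac cycle is the detector's fiducial point.
#'
#' @param signal a [sampled_signal()] (or numeric vector with unit
#'   spacing), length >= 3.
#' @return the APG, same class and length as the input.
#' @export
second_derivative <- function(signal) {
  is_sig <- inherits(signal, "sampled_signal")
  x <- if (is_sig) signal$values else signal
  n <- length(x)
  if (n < 3L) stop("signal must have length >= 3")
  if (anyNA(x))
    stop("signal has missing samples; call fill_missing() first")
  dt <- if (is_sig) 1 / signal$sampling_rate else 1
  d2 <- numeric(n)
  d2[2:(n - 1L)] <- (x[1:(n - 2L)] - 2 * x[2:(n - 1L)] + x[3:n]) / dt^2
  d2[1L] <- (x[1L] - 2 * x[2L] + x[3L]) / dt^2
  d2[n] <- (x[n - 2L] - 2 * x[n - 1L] + x[n]) / dt^2
  if (is_sig) signal_with_values(signal, d2) else d2
}

#' Repair missing sample slots by linear interpolation
#'
#' Interior gaps are filled by linear interpolation between the flanking
#' observed samples; leading/trailing gaps are held at the nearest
#' observed value. The missing mask is preserved so the data-loss
#' statistic still reflects the original loss.
#'
#' @param signal a [sampled_signal()] with at least one observed sample.
#' @return signal with values repaired and the original `missing_mask`.
#' @export
fill_missing <- function(signal) {
  stop_if_not_signal(signal)
  x <- signal$values
  if (all(is.na(x))) stop("all samples are missing; nothing to interpolate")
  if (!anyNA(x)) return(signal)
  obs <- which(!is.na(x))
  filled <- stats::approx(obs, x[obs], xout = seq_along(x), method = "linear",
                          rule = 2)$y
  sampled_signal(filled, signal$sampling_rate, signal$start_time,
                 missing_mask = signal$missing_mask)
}

#' Full PPG conditioning chain
#'
#' Missing-slot repair, moving average, airPLS baseline correction,
#' low-pass IIR, second derivative — in that order. Returns the APG ready
#' for beat detection.
#'
#' @param signal raw PPG as a [sampled_signal()].
#' @param spec a [filter_spec()].
#' @return the APG as a [sampled_signal()] (missing mask preserved).
#' @export
preprocess_ppg <- function(signal, spec = filter_spec()) {
  stop_if_not_signal(signal)
  x <- fill_missing(signal)
  x <- moving_average(x, spec$ma_window)
  x <- baseline_correct_airpls(x, lambda = spec$airpls_lambda,
                               max_iter = spec$airpls_max_iter)
  x <- lowpass_iir(x, spec)
  second_derivative(x)
}
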