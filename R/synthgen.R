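#' Scenario preset for synthetic recordings
#'
#' A preset bundles the target interval statistics of one measurement
#' scenario (posture / breathing pattern) with the simulation knobs used
#' to emulate it: respiratory sinus arrhythmia (RSA) and sample dropout.
#' The four shipped presets (`sitting`, `sitting_deep_breathing`,
#' `standing`, `supine`) target the ECG-derived cohort means of a
#' 30-subject validation study of a 40 Hz wireless pulse oximeter; deep
#' breathing is paced at 10 breaths/min.
#'
#' @param name scenario name, one of `sitting`, `sitting_deep_breathing`,
#'   `standing`, `supine` (free names are allowed for custom presets).
#' @param target_mean_ibi target mean inter-beat interval, ms.
#' @param target_sdnn target SDNN of the stochastic interval component, ms.
#' @param target_rmssd target RMSSD of the stochastic interval component,
#'   ms; must satisfy `target_rmssd <= 2 * target_sdnn` (attainable by a
#'   stationary process since RMSSD^2 = 2 SDNN^2 (1 - rho1), rho1 in
#'   \[-1, 1\]).
#' @param respiration_rate breaths per minute driving the RSA sinusoid.
#' @param rsa_amplitude RSA sinusoid amplitude, ms.
#' @param dropout_rate expected fraction of missing sample slots, default
#'   0.01 (matching the ~1.0% data loss observed across postures).
#' @param duration nominal recording duration in seconds, default 180
#'   (3-minute ultra-short-term protocol).
#' @return an object of class `scenario_preset`.
#' @export
scenario_preset <- function(name, target_mean_ibi, target_sdnn,
                            target_rmssd, respiration_rate = 15,
                            rsa_amplitude = 0, dropout_rate = 0.01,
                            duration = 180) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm))
    as.numeric(v)
  }
  target_mean_ibi <- num1(target_mean_ibi, "target_mean_ibi")
  target_sdnn <- num1(target_sdnn, "target_sdnn")
  target_rmssd <- num1(target_rmssd, "target_rmssd")
  if (target_mean_ibi <= 0) stop("`target_mean_ibi` must be > 0")
  if (target_sdnn < 0 || target_rmssd < 0)
    stop("`target_sdnn` and `target_rmssd` must be >= 0")
  if (target_rmssd > 2 * target_sdnn + 1e-12)
    stop("`target_rmssd` must not exceed 2 * target_sdnn ",
         "(unattainable by a stationary process)")
  dropout_rate <- num1(dropout_rate, "dropout_rate")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)")
  structure(
    list(name = name, target_mean_ibi = target_mean_ibi,
         target_sdnn = target_sdnn, target_rmssd = target_rmssd,
         respiration_rate = num1(respiration_rate, "respiration_rate"),
         rsa_amplitude = num1(rsa_amplitude, "rsa_amplitude"),
         dropout_rate = dropout_rate,
         duration = num1(duration, "duration")),
    class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf(paste0("<scenario_preset> %s: IBI %.2f ms, SDNN %.2f ms, ",
                     "RMSSD %.2f ms, %g br/min (RSA %g ms), dropout %.1f%%, %g s\n"),
              x$name, x$target_mean_ibi, x$target_sdnn, x$target_rmssd,
              x$respiration_rate, x$rsa_amplitude,
              100 * x$dropout_rate, x$duration))
  invisible(x)
}

#' Load the scenario preset registry
#'
#' Reads a registry of named scenario presets from a key-value (DCF)
#' config file. With `path = NULL` the registry shipped with the package
#' (the four study scenarios) is used.
#'
#' @param path path to a DCF preset file, or `NULL` for the shipped
#'   registry.
#' @return named list of [scenario_preset()] objects.
#' @export
scenario_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scenarios.dcf", package = "prvkit",
                        mustWork = TRUE)
  tbl <- read.dcf(path)
  needed <- c("name", "target_mean_ibi", "target_sdnn", "target_rmssd",
              "respiration_rate", "rsa_amplitude", "dropout_rate",
              "duration")
  missing_cols <- setdiff(needed, colnames(tbl))
  if (length(missing_cols))
    stop("preset file is missing fields: ",
         paste(missing_cols, collapse = ", "))
  out <- lapply(seq_len(nrow(tbl)), function(i) {
    scenario_preset(
      name = tbl[i, "name"],
      target_mean_ibi = as.numeric(tbl[i, "target_mean_ibi"]),
      target_sdnn = as.numeric(tbl[i, "target_sdnn"]),
      target_rmssd = as.numeric(tbl[i, "target_rmssd"]),
      respiration_rate = as.numeric(tbl[i, "respiration_rate"]),
      rsa_amplitude = as.numeric(tbl[i, "rsa_amplitude"]),
      dropout_rate = as.numeric(tbl[i, "dropout_rate"]),
      duration = as.numeric(tbl[i, "duration"]))
  })
  names(out) <- tbl[, "name"]
  out
}

#' Fetch one shipped scenario preset by name
#'
#' @param name scenario name.
#' @param path optional preset registry path (see [scenario_presets()]).
#' @return a [scenario_preset()].
#' @export
get_scenario <- function(name, path = NULL) {
  reg <- scenario_presets(path)
  if (!name %in% names(reg))
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[name]]
}

#' Generate a ground-truth inter-beat interval series
#'
#' Draws a stationary interval process
#' `IBI_k = mu + RSA * sin(2 pi f_resp t_k) + eps_k` where `eps_k` is an
#' AR(1) process whose marginal SD and lag-1 autocorrelation are solved
#' from the preset's SDNN/RMSSD targets via
#' `RMSSD^2 = 2 SDNN^2 (1 - rho1)`. The RSA sinusoid is evaluated at the
#' nominal beat times `t_k = (k-1) mu / 1000` s. Intervals are clipped to
#' the physiologically plausible range \[300, 2000\] ms.
#'
#' @param preset a [scenario_preset()].
#' @param n_beats number of intervals to draw, >= 2.
#' @param seed RNG seed for reproducibility (`NULL` = use current stream).
#' @return an [ibi_series()] with `origin = "truth"`.
#' @export
generate_ibi_series <- function(preset, n_beats, seed = NULL) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 2)
    stop("`n_beats` must be >= 2")
  n <- as.integer(n_beats)
  mu <- preset$target_mean_ibi
  sdnn <- preset$target_sdnn
  rmssd <- preset$target_rmssd

  eps <- if (sdnn == 0) {
    if (rmssd != 0)
      stop("target_rmssd must be 0 when target_sdnn is 0")
    numeric(n)
  } else {
    rho <- 1 - rmssd^2 / (2 * sdnn^2)
    if (rho < -1 || rho > 1)
      stop(sprintf("implied lag-1 autocorrelation %.3f outside [-1, 1]", rho))
    with_seed(seed, {
      innov_sd <- sdnn * sqrt(max(0, 1 - rho^2))
      e1 <- stats::rnorm(1L, 0, sdnn)
      if (n > 1L) {
        innov <- stats::rnorm(n - 1L, 0, innov_sd)
        c(e1, as.numeric(stats::filter(innov, rho, method = "recursive",
                                       init = e1)))
      } else e1
    })
  }

  t_nominal <- (seq_len(n) - 1L) * mu / 1000
  f_resp <- preset$respiration_rate / 60
  ibi <- mu + preset$rsa_amplitude * sin(2 * pi * f_resp * t_nominal) + eps
  ibi <- pmin(pmax(ibi, 300), 2000)
  ibi_series(ibi, origin = "truth")
}

#' Two-lobe beat pulse template
#'
#' Parametric pulse shape used when rendering a PPG waveform: an
#' asymmetric systolic lobe (fast rise, slower fall, so the acceleration
#' waveform has a single dominant positive peak per beat) plus a smaller,
#' wider dicrotic lobe. All times in ms relative to pulse onset.
#'
#' @param width_ms total template support, default 450 ms.
#' @param systolic_peak_ms time of the systolic maximum.
#' @param rise_ms,fall_ms Gaussian SDs of the systolic rise and fall.
#' @param dicrotic_delay_ms,dicrotic_width_ms location and Gaussian SD of
#'   the dicrotic lobe.
#' @param dicrotic_rel_amplitude dicrotic amplitude relative to systolic.
#' @param amplitude systolic amplitude (arbitrary units).
#' @return an object of class `beat_template`.
#' @export
beat_template <- function(width_ms = 450, systolic_peak_ms = 120,
                          rise_ms = 45, fall_ms = 70,
                          dicrotic_delay_ms = 240, dicrotic_width_ms = 110,
                          dicrotic_rel_amplitude = 0.12, amplitude = 1) {
  stopifnot(width_ms > 0, systolic_peak_ms > 0, rise_ms > 0, fall_ms > 0)
  structure(list(width_ms = width_ms, systolic_peak_ms = systolic_peak_ms,
                 rise_ms = rise_ms, fall_ms = fall_ms,
                 dicrotic_delay_ms = dicrotic_delay_ms,
                 dicrotic_width_ms = dicrotic_width_ms,
                 dicrotic_rel_amplitude = dicrotic_rel_amplitude,
                 amplitude = amplitude),
            class = "beat_template")
}

# Evaluate a template at times t_ms (ms since pulse onset). A raised-
# cosine taper over the last 35% of the support brings the pulse smoothly
# to zero, so truncation adds no spurious curvature to the APG.
eval_template <- function(template, t_ms) {
  tp <- template$systolic_peak_ms
  s <- ifelse(t_ms < tp,
              exp(-(t_ms - tp)^2 / (2 * template$rise_ms^2)),
              exp(-(t_ms - tp)^2 / (2 * template$fall_ms^2)))
  d <- template$dicrotic_rel_amplitude *
    exp(-(t_ms - template$dicrotic_delay_ms)^2 /
          (2 * template$dicrotic_width_ms^2))
  out <- template$amplitude * (s + d)
  w <- template$width_ms
  t0 <- 0.65 * w
  taper <- ifelse(t_ms <= t0, 1,
                  0.5 * (1 + cos(pi * (t_ms - t0) / (w - t0))))
  out <- out * taper
  out[t_ms < 0 | t_ms > w] <- 0
  out
}

# Offset (in samples) of the template's dominant APG peak from its
# onset, at the given sampling rate. The fiducial is defined on the
# band-limited pulse (5-sample moving average, matching the default
# conditioning of a 40 Hz chain): the curvature maximum the detector can
# actually resolve, not the ideal continuous-time one.
template_apg_offset <- function(template, sampling_rate) {
  t_ms <- seq(0, template$width_ms, by = 1000 / sampling_rate)
  s <- eval_template(template, t_ms)
  if (all(s == 0)) return(0L)
  s <- c(0, 0, 0, s, 0, 0, 0)               # zero context around the pulse
  s <- stats::filter(s, rep(1 / 5, 5), sides = 2)
  s <- as.numeric(s)[3:(length(s) - 2)]     # 1 sample of pad on each side
  n <- length(s)
  if (n < 3L) return(0L)
  d2 <- s[-c(1L, 2L)] - 2 * s[-c(1L, n)] + s[-c(n - 1L, n)]
  which.max(d2) - 1L  # account for the retained one-sample lead pad
}

#' Render a PPG waveform from an interval series
#'
#' Places one pulse template at the onset of every interval, samples the
#' sum on a uniform grid, and adds Gaussian noise and sinusoidal baseline
#' wander. Also returns the ground-truth event sample indices: the
#' location of each beat's dominant APG (second-derivative) peak, which is
#' where the beat detector is expected to fire.
#'
#' @param ibi an [ibi_series()]; one beat is rendered per interval, at the
#'   interval's onset.
#' @param sampling_rate sampling rate in Hz, >= 20 (default 40, the
#'   emulated sensor's rate).
#' @param template a [beat_template()].
#' @param noise_sd SD of additive Gaussian noise (amplitude units).
#' @param wander_amplitude,wander_freq amplitude and frequency of the
#'   sinusoidal baseline wander.
#' @param seed RNG seed (`NULL` = current stream).
#' @return list with elements `signal` (a [sampled_signal()]) and
#'   `truth_indices` (integer sample indices, 1-based, one per beat).
#' @export
render_ppg <- function(ibi, sampling_rate = 40, template = beat_template(),
                       noise_sd = 0, wander_amplitude = 0,
                       wander_freq = 0.25, seed = NULL) {
  stop_if_not_ibi(ibi)
  stopifnot(inherits(template, "beat_template"))
  if (sampling_rate < 20)
    stop("`sampling_rate` must be >= 20 Hz")
  if (template$amplitude != 0 && template$width_ms > min(ibi$intervals))
    stop(sprintf(paste0("template width (%g ms) exceeds the shortest ",
                        "interval (%g ms): pulses would merge"),
                 template$width_ms, min(ibi$intervals)))

  duration <- sum(ibi$intervals) / 1000
  n <- as.integer(ceiling(duration * sampling_rate))
  t_s <- (seq_len(n) - 1L) / sampling_rate
  x <- numeric(n)

  onset_idx <- as.integer(round(ibi$event_times * sampling_rate)) + 1L
  tpl_len <- as.integer(floor(template$width_ms / 1000 * sampling_rate)) + 1L
  tpl <- eval_template(template, (seq_len(tpl_len) - 1L) * 1000 / sampling_rate)
  for (i in seq_along(onset_idx)) {
    i0 <- onset_idx[i]
    i1 <- min(n, i0 + tpl_len - 1L)
    if (i0 > n) next
    x[i0:i1] <- x[i0:i1] + tpl[seq_len(i1 - i0 + 1L)]
  }

  if (wander_amplitude != 0)
    x <- x + wander_amplitude * sin(2 * pi * wander_freq * t_s)
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))

  truth <- onset_idx + template_apg_offset(template, sampling_rate)
  truth <- truth[truth <= n]
  list(signal = sampled_signal(x, sampling_rate),
       truth_indices = as.integer(truth))
}

#' Mark a random subset of sample slots as missing
#'
#' Emulates wireless transmission loss: each expected sample slot is
#' dropped independently with probability `dropout_rate` (the measured
#' data-loss percentage is then `100 * dropout_rate` in expectation).
#' Setting `burst_mean > 1` instead drops geometric-length bursts with the
#' same expected overall loss, mimicking packet-loss bursts; the default
#' is i.i.d. per-slot loss.
#'
#' @param signal a [sampled_signal()].
#' @param dropout_rate fraction of slots to drop, in \[0, 0.5).
#' @param seed RNG seed (`NULL` = current stream).
#' @param burst_mean mean burst length in slots (1 = independent slots).
#' @return the signal with dropped slots set `NA` and flagged in
#'   `missing_mask`.
#' @export
apply_dropout <- function(signal, dropout_rate, seed = NULL,
                          burst_mean = 1) {
  stop_if_not_signal(signal)
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 0.5)
    stop("`dropout_rate` must lie in [0, 0.5)")
  if (burst_mean < 1) stop("`burst_mean` must be >= 1")
  n <- length(signal$values)
  drop <- with_seed(seed, {
    if (burst_mean == 1) {
      stats::runif(n) < dropout_rate
    } else {
      starts <- stats::runif(n) < dropout_rate / burst_mean
      lens <- 1L + stats::rgeom(n, prob = 1 / burst_mean)
      d <- logical(n)
      for (i in which(starts)) d[i:min(n, i + lens[i] - 1L)] <- TRUE
      d
    }
  })
  mask <- signal$missing_mask | drop
  vals <- signal$values
  vals[mask] <- NA_real_
  sampled_signal(vals, signal$sampling_rate, signal$start_time,
                 missing_mask = mask)
}

#' Simulate one full synthetic recording
#'
#' Convenience wrapper: draws a truth interval series from a scenario
#' preset, renders the PPG waveform, and applies sample dropout. Enough
#' beats are drawn to cover `duration`, then the series is trimmed to the
#' recording length.
#'
#' @param scenario a [scenario_preset()] or the name of a shipped one.
#' @param duration recording length in seconds (default: preset value).
#' @param sampling_rate sensor rate in Hz, default 40.
#' @param template a [beat_template()].
#' @param noise_sd,wander_amplitude,wander_freq waveform nuisance levels
#'   (defaults: mild noise, slow respiratory-band wander).
#' @param dropout_rate slot-loss fraction (default: preset value).
#' @param seed RNG seed; all internal draws derive from it.
#' @return list with `signal` (dropout applied), `truth_ibi` (trimmed
#'   [ibi_series()]), `truth_indices`, and `preset`.
#' @export
simulate_recording <- function(scenario, duration = NULL,
                               sampling_rate = 40,
                               template = beat_template(),
                               noise_sd = 0.005, wander_amplitude = 0.3,
                               wander_freq = 0.25, dropout_rate = NULL,
                               seed = NULL) {
  preset <- if (is.character(scenario)) get_scenario(scenario) else scenario
  stopifnot(inherits(preset, "scenario_preset"))
  if (is.null(duration)) duration <- preset$duration
  if (is.null(dropout_rate)) dropout_rate <- preset$dropout_rate

  n_guess <- ceiling(duration * 1000 / preset$target_mean_ibi * 1.3) + 5L
  seeds <- derive_seeds(seed, 3L)
  ibi <- generate_ibi_series(preset, n_guess, seed = seeds[[1L]])
  keep <- cumsum(ibi$intervals) <= duration * 1000
  if (sum(keep) < 2L) stop("duration too short for the preset's mean IBI")
  ibi <- ibi_series(ibi$intervals[keep], origin = "truth")

  # pulses shorten when intervals do: shrink the whole template
  # proportionally if the shortest drawn interval is tighter than it
  shrink <- min(1, 0.95 * min(ibi$intervals) / template$width_ms)
  if (shrink < 1) {
    for (f in c("width_ms", "systolic_peak_ms", "rise_ms", "fall_ms",
                "dicrotic_delay_ms", "dicrotic_width_ms"))
      template[[f]] <- template[[f]] * shrink
  }

  rendered <- render_ppg(ibi, sampling_rate = sampling_rate,
                         template = template, noise_sd = noise_sd,
                         wander_amplitude = wander_amplitude,
                         wander_freq = wander_freq, seed = seeds[[2L]])
  signal <- apply_dropout(rendered$signal, dropout_rate, seed = seeds[[3L]])
  list(signal = signal, truth_ibi = ibi,
       truth_indices = rendered$truth_indices, preset = preset)
}

# Derive k child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list((as.double(seed) * 48271 + 7919 * seq_len(k)) %% 2147483647)
}
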