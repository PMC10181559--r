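# Shared fixtures: everything is generated in code, no stored data.

# A clean rendered recording from a constant interval series; long enough
# for at least one 20-s detector window.
clean_recording <- function(n_beats = 40, interval_ms = 800,
                            template = beat_template(), seed = 1) {
  ibi <- ibi_series(rep(interval_ms, n_beats))
  render_ppg(ibi, sampling_rate = 40, template = template,
             noise_sd = 0, wander_amplitude = 0, seed = seed)
}

# Detection scores against truth indices with a sample tolerance.
detection_scores <- function(event_indices, truth_indices, tol = 2) {
  hit <- vapply(truth_indices,
                function(t) min(abs(event_indices - t)) <= tol, logical(1))
  tp <- sum(hit)
  fp <- length(event_indices) - tp
  fn <- length(truth_indices) - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = tp / length(truth_indices),
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# Paired cohort with a known additive bias on the PPG side.
synthetic_cohort <- function(n_subjects = 20, bias = 0, noise_sd = 1,
                             seed = 1,
                             scenarios = c("sitting", "standing"),
                             indicators = c("HR", "SDNN")) {
  set.seed(seed)
  grid <- expand.grid(subject_id = seq_len(n_subjects),
                      scenario = scenarios, indicator = indicators,
                      stringsAsFactors = FALSE)
  base <- 50 + 10 * as.integer(factor(grid$indicator)) +
    stats::rnorm(nrow(grid), 0, 8)
  grid$ecg_value <- base
  grid$ppg_value <- base - bias + stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}

# Printed cohort-table cells (reference ECG mean, test PPG mean, printed
# DF% / P bias, decimals printed) used by the worked-example checks.
published_cells <- function() {
  cells <- rbind(
    c(81.44, 81.23, 0.26, 0.3, 2, 1),
    c(757.16, 758.69, 0.20, -0.2, 1, 1),
    c(47.94, 52.21, 8.91, -8.2, 2, 1),
    c(38.33, 42.58, 11.11, -10.0, 2, 0),
    c(88.58, 88.29, 0.34, 0.3, 2, 1),
    c(733.66, 728.62, 0.69, 0.7, 2, 1),
    c(63.15, 61.57, 2.50, 2.6, 1, 1),
    c(24.39, 33.37, 36.82, 26.9, 2, 1),
    c(83.28, 83.81, 0.63, -0.6, 2, 1),
    c(733.66, 728.62, 0.69, 0.7, 2, 1),
    c(63.15, 61.57, 2.50, 2.6, 1, 1),
    c(46.55, 51.58, 10.80, -9.7, 1, 1),
    c(72.71, 72.38, 0.45, 0.5, 2, 1),
    c(851.51, 855.18, 0.43, -0.4, 2, 1),
    c(48.00, 55.72, 16.10, -13.9, 1, 1),
    c(49.52, 46.69, 5.70, 6.0, 1, 0))
  colnames(cells) <- c("ecg", "ppg", "df_printed", "pbias_printed",
                       "df_dec", "pbias_dec")
  as.data.frame(cells)
}
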