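---
title: "Measuring pulse rate variability from low-rate PPG: models, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pulse rate variability from low-rate PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prvkit)
```

## The measurement problem

Heart rate variability (HRV) is conventionally measured from ECG R–R
intervals. A fingertip pulse oximeter measures the same beat-to-beat
timing optically — pulse rate variability (PRV) — at a fraction of the
cost, which matters for remote monitoring in low-resource settings. The
catch is that consumer PPG devices sample slowly (40 Hz here, i.e.
25 ms timing quantization), lose packets over the wireless link, and
present a smooth waveform whose fiducial points are harder to localize
than an R peak. `prvkit` implements the full measurement chain for
3-minute ("ultra-short-term") recordings and the statistical machinery
to judge, over a cohort, whether the PPG-derived indicators agree with
ECG-derived ones.

The chain is: **condition** the raw PPG (moving average → airPLS
baseline correction → 6th-order Butterworth low-pass at 18 Hz), take
the **second derivative** (the acceleration plethysmogram, APG, whose
dominant positive peak per cardiac cycle marks the systolic upstroke),
**detect** those peaks with a windowed adaptive-threshold rule, convert
peak-to-peak sample distances to intervals (`PP = Δφ/Θ · 1000` ms at
sampling rate Θ), and **summarize**:

* mean HR `= 60000 / mean(IBI)` (bpm),
* SDNN `= sd(IBI)` (sample SD, N−1),
* RMSSD `= sqrt(mean(diff(IBI)^2))`,
* data loss `= 100 · missing slots / expected slots` (%).

A `literal` RMSSD variant dividing by N−2 preserves a printed form
found in the source material; the two differ by `sqrt((N-1)/(N-2))`
and nothing downstream depends on the choice.

## The beat detector

Candidates are strict local maxima of the APG. A candidate at sample
`k` becomes an event when its local-peak statistic exceeds a threshold
θ:

```
Δy(k) = y(k) − ref(k)  >  θ
```

Three decisions here were genuinely open, and each default was chosen
after the alternative measurably failed:

* **Comparison span.** `ref(k)` is built from the samples ±0.25 s away
  (`comparison_halfwidth`, one quarter of a half-sampling-frequency
  span), *not* from samples half a data window away. Δy is then a local
  prominence: the secondary positive APG lobes that trail each systolic
  peak sit next to a much larger neighbor and receive a negative Δy.
  With a distant reference the statistic degenerates to the raw
  amplitude and every secondary lobe fires.
* **Reference strategy.** Default `both_sides`: the candidate must
  exceed *both* flanking samples by θ (`ref = max` of the two). The
  `mean` variant is also available but is fragile in exactly one way:
  the APG's deep negative valley, when it lands on one flank, adds half
  its depth to the prominence of whatever ripple sits opposite —
  manufacturing false events out of noise. `one_sided` reproduces the
  literal single-sample comparison. Flanks clip to the record edges;
  clipping to the 20-s window instead makes peaks at window seams
  compare against themselves.
* **Threshold.** θ is the 0.6 quantile of the window's positive APG
  amplitudes (20-s windows), which makes detection invariant to
  amplitude rescaling — PPG gain is arbitrary. A `fixed` absolute θ is
  available for literal reproduction.

A 250 ms refractory rule (240 bpm ceiling) then keeps the larger of
any two events closer than the gap; plateau ties resolve to the first
sample. Detected events are indexed on the full uniform grid including
repaired dropout slots, so interval timing is unaffected by gap repair.

Downstream, `clean_intervals()` rejects intervals outside
[300, 2000] ms or deviating more than 30% from an 11-point running
median — the practical guard against the occasional split or merged
beat that dropout repair produces.

## The synthetic world

No raw recordings are available from the validation study the presets
emulate, so the generator *is* the test bed, and its assumptions are
stated rather than hidden:

* **Intervals.** `IBI_k = μ + RSA·sin(2π f_resp t_k) + ε_k`, with ε an
  AR(1) process whose marginal SD and lag-1 autocorrelation are solved
  from the SDNN/RMSSD targets via `RMSSD² = 2·SDNN²·(1−ρ₁)` — the
  simplest stationary process in which the two indicators are
  independently tunable, making parameter recovery a closed-form test.
  Targets with implied ρ₁ outside [−1, 1] (RMSSD > 2·SDNN) are
  rejected as unattainable by any stationary process. The RSA sinusoid
  is evaluated at nominal beat times `t_k = (k−1)μ/1000`; intervals are
  clipped to [300, 2000] ms.
* **Presets.** Four scenarios ship in `inst/extdata/scenarios.dcf`,
  targeting the ECG-derived cohort means of the emulated study:
  sitting (μ 757.16, SDNN 47.94, RMSSD 38.33 ms), standing (733.66,
  63.15, 24.39), supine (851.51, 48, 49.52), and sitting with deep
  breathing (733.66, 63.15, 46.55) paced at 10 breaths/min with a
  40 ms RSA amplitude (our choice; the study reports no amplitude).
  The cohort SD columns are treated as between-subject spread and are
  not simulated within a recording. Dropout defaults to 1% of sample
  slots, i.i.d. (the observed loss was 1.0% across postures); a
  geometric-burst option exists for packet-loss-like gaps but defaults
  off.
* **Waveform.** Each beat is a fixed two-lobe template: an asymmetric
  systolic lobe (Gaussian rise σ 45 ms, fall σ 70 ms, peak at 120 ms)
  plus a broad, weak dicrotic shoulder (σ 110 ms at 240 ms, 12%
  relative amplitude), tapered smoothly to zero over the last 35% of
  its 450 ms support. This is deliberately what a 40 Hz sensor can
  resolve: a sharp dicrotic notch is invisible at this rate, and —
  matching the detector's core assumption — the template's APG has one
  dominant positive peak per beat. Sharper dicrotic shapes leave a
  trailing curvature lobe at up to 60% of the main peak, which no
  threshold consistent with the 0.6-quantile policy separates. The
  ground-truth event index of each beat is the curvature maximum of
  the *band-limited* pulse (template smoothed by the default 5-sample
  moving average): the fiducial the chain can actually see.
* **Nuisance defaults.** White noise at 0.5% of pulse amplitude,
  baseline wander of 0.3 amplitude at 0.25 Hz, 1% dropout. The noise
  level is set by the requirement that the default world be one where
  the instrument demonstrably works — the emulated study reports
  HR/IBI difference factors of 0.2–0.7%, impossible if beat detection
  were failing. At 2% noise the second derivative (which amplifies
  high frequencies roughly 40-fold at this rate, the 18 Hz low-pass
  sitting too close to the 20 Hz Nyquist to help) already produces
  spurious diastolic events.

What a green test does **not** establish: robustness to motion
artifacts, waveform morphology changes (arrhythmia, vascular ageing),
bursty packet loss, or sensor saturation — none of which the generator
emulates. The synthetic world validates the *pipeline arithmetic and
its stated assumptions*, not the device.

## Numerical choices

* **Butterworth design** is done in-package (no signal-processing
  package is available in the target environment): analog prototype
  poles, bilinear transform with prewarping, DC-gain normalization;
  verified against the analytic magnitude response
  `|H| = 1/sqrt(1 + (tan(πf/fs)/tan(πfc/fs))^{2n})` to 6 decimals.
  Offline mode filters forward and backward (zero net phase, squared
  magnitude) with odd-reflection edge padding; streaming mode is a
  single causal pass that reports its passband group delay. The 18 Hz
  cutoff at 40 Hz sampling is kept as specified but is configurable —
  at 0.9 of Nyquist it is nearly transparent, which is also why the
  noise ceiling above is low.
* **airPLS** solves the penalized least-squares baseline with a sparse
  banded Cholesky (`Matrix`), λ = 1e5, ≤ 15 iterations, weights zeroed
  above the running baseline and exponentially reweighted below, edge
  anchors as in the classic algorithm. The convergence scale is
  centered (`Σ|y − mean(y)|`) so that the output is exactly invariant
  to a constant offset of the input — the uncentered classic rule
  changes its iteration count under offsets.
* **Second derivative** is the central second difference over the
  squared sampling interval, one-sided at the endpoints (exact for
  quadratics, < 2% error at 1 Hz/40 Hz).
* **Scheirer–Ray–Hare** ranks all values jointly (midranks for ties)
  and decomposes the rank sum of squares; `H = SS_effect /
  (SS_total/(n−1))` referred to χ². Computing `MS_total` from the
  midrank SS applies the standard tie correction implicitly — the
  midrank `SS_total` equals `(n³−n)/12` times the tie divisor — and
  makes the statistic reduce *exactly* to base R's `kruskal.test`,
  ties included, when one factor is constant. Dividing by the tie
  divisor again, as a literal reading of some formulations suggests,
  double-corrects and breaks that reduction.
* **Levene's gate** is the classical mean-centered form
  (median-centered Brown–Forsythe by option); degenerate inputs with
  identical deviations return homogeneity rather than 0/0.
* **Wilcoxon branch** of the paired comparison drops zero differences,
  uses the exact distribution below 25 nonzero pairs and the
  continuity-corrected normal approximation above; the Shapiro–Wilk
  gate at α = 0.05 selects the paired t-test when normality is not
  rejected. Dunn's post hoc uses joint midranks with tie correction
  and Holm adjustment by default (`none` for literal reproduction).
* **DF% and P bias** are reconstructed conventions:
  `DF% = 100·|ē−p̄|/ē` and `P bias = 100·(ē−p̄)/p̄`, validated against
  27 of the 32 printed cohort-table cells at half a printed ulp (the
  five exceptions are printing artifacts in the source tables,
  including one sign anomaly that matches in magnitude).

## Known limitations

* The first rendered beat sits in the moving-average warm-up region at
  the record edge; its fiducial lands up to 2 samples late. Timing
  claims of ±1 sample therefore hold for post-warm-up beats; detection
  scoring at ±2 samples covers every beat.
* At 40 Hz the interval quantization is 25 ms; recovered SDNN/RMSSD
  carry quantization error of that order, which is the accuracy floor
  of the whole approach, not of this implementation.
* Frequency-domain indicators (LF/HF) are out of scope; they require
  sampling rates this class of device does not provide.
* Cohort-level SDs, RMSEs and p-values of the emulated study are not
  reproducible without the (unavailable) raw subject data; the
  agreement workflow is validated on synthetic cohorts with known bias
  instead.
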