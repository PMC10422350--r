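---
title: "Methods: signature-matrix fusion of lung sound and ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-matrix fusion of lung sound and ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respsig)
```

## The problem and the model

A chest-mounted wearable records two synchronized channels at 4 kHz: a
piezoelectric lung-sound signal and an ECG. Both carry respiratory
information — breath sounds grow louder with tidal volume, and ECG beat
amplitudes are modulated by respiration phase (respiratory sinus
arrhythmia: beat heights drop during inhalation). `respsig` turns each
breathing cycle of each channel into a scalar tidal-volume proxy (a
polynomial-envelope AUC) and then fuses the two channels into a compact
3×3 probability map per cycle, classified against condition templates.

The chain assumes metronome-paced breathing: cycles of known, fixed length
(default 4 s — 2 s inhale, 2 s exhale) whose boundaries come from
annotations, not from peak detection. This matches a controlled protocol
(deep 1000 mL / moderate 750 mL / shallow 500 mL breathing, and simulated
coughing); free-breathing segmentation is out of scope.

## Stage by stage

**Band splitting.** The sound channel is analysed in a < 2 Hz band (chest
motion) and a > 150 Hz band (breath sounds); the ECG in a < 150 Hz band
(cardiac waveform) and a > 150 Hz band. The filter family and order are a
package choice: 4th-order Butterworth run forward and backward
(`signal::filtfilt`), because zero phase keeps envelope features aligned
with the cycle grid that the per-cycle fits depend on. The effective
roll-off of the forward–backward cascade is that of an 8th-order filter,
comfortably exceeding 40 dB one decade outside each band. The upper edge of
the "high" bands is the Nyquist frequency; no upper cutoff is imposed.

**Moving variance.** Envelopes are the population variance (divide by *n*)
over a sliding 1000-sample window — 250 ms at 4 kHz — with a default hop of
one sample, so the envelope stays on the signal's own time base. Population
rather than sample variance is an arbitrary constant factor on an
arbitrary-units envelope; it is fixed and tested rather than consequential.
The implementation subtracts the overall mean and uses running sums
(O(*n*)); windowed variances are clamped at zero against roundoff.

**Per-cycle polynomial AUC.** Each cycle's envelope points — trimmed by half
a variance window at each end, to keep filter and window edge effects out of
the fit — are fitted with a polynomial of order exactly 7 by least squares.
Time is normalized to [−1, 1] per cycle: an order-7 Vandermonde system on
absolute seconds is numerically ill-conditioned, on the normalized axis it
is benign. The AUC is the *analytic* integral of the fitted polynomial with
negative excursions clipped to zero (a variance envelope is nonnegative, but
an order-7 fit can undershoot): real roots inside the span partition it into
sign-constant segments, and positive segments are integrated exactly. The
within-cycle cumulative AUC is the same clipped integral evaluated on a
grid, hence nondecreasing by construction, with its last value equal to the
AUC; the derivative series is its successive differences, which telescope
back exactly. Fitting from the polynomial rather than the raw envelope is
one of two defensible readings of the procedure; the raw-envelope trapezoid
is available by integrating the envelope directly, but the fitted form is
the default because the downstream statistics are defined on the fitted
curves.

**Signature matrices.** Each cycle's two cumulative-AUC curves are sampled
at `windows_per_matrix = 40` points — at 4 kHz, one frame per 40 samples is
100 frames per second of signal — and each (sound, ECG) pair is assigned to
a 3×3 cell: columns are the sound zones, rows the ECG zones. Zones are
half-open and lower-inclusive (`value < t1` → zone 1, `t1 ≤ value < t2` →
zone 2, else zone 3); the convention is arbitrary but fixed and tested. The
zone thresholds ("preset intervals") are a genuinely open design point; the
default is reproducible and data-driven — per-channel tertiles of the pooled
template-condition cumulative values — and the thresholds are persisted
inside the template library JSON so targets are always zoned identically to
the templates that will judge them. Explicit thresholds can be supplied
instead. Freshly built matrices count every frame and sum to exactly 1. The
shipped reference matrices (`reference_signatures()`) sum to about 0.9895 —
consistent with one frame in ~95 left uncounted — so fixtures are validated
under a "sum ≤ 1" contract and never renormalized: the uncounted-frame
convention of the source material is not inferable and is left as is.

**Templates and classification.** A condition's template is the
element-wise mean of its per-cycle matrices. A target is assigned the label
of the template minimizing the sum of squared element differences
(`sse()`); ties are broken by library insertion order and flagged. The SSE
is symmetric, nonnegative, and zero only for identical matrices.

**Group statistics.** Two-group one-way ANOVA from the sum-of-squares
definitions, df = (1, n−2), with the upper-α F critical value from
`stats::qf` and an explicit degenerate path (both groups constant but
different: F = ∞, p = 0, flagged; identical constants: error). Group sizes
are always taken from the data. Box-plot summaries use linear-interpolation
quartiles (`stats::quantile` type 7) and the 1.5 × IQR outlier rule.

## The simulator: what it does and does not emulate

The generator produces the statistical structure the pipeline *measures*,
with arbitrary ADC-like units (the method uses only relative quantities):

* Sound: band-limited (150–1000 Hz) noise bursts gated over the inhale
  half, amplitude `sound_burst_gain(tidal_volume)` (default linear,
  `tv/1000`), normalized per cycle so realized burst energy is an exact,
  strictly increasing function of tidal volume; plus a < 2 Hz chest-motion
  sinusoid scaled by tidal volume. Coughs add a ~0.5 s broadband transient
  (amplitude 2.5, above the deepest breath) and a larger low-frequency
  excursion.
* ECG: a periodic PQRST template built from Gaussian bumps at 75 bpm
  (an integer 5 beats per 4 s cycle, so every cycle sees the same beat
  phases), with beats whose R peak falls in the inhale half scaled by
  `1 − rsa_modulation_depth` (default 0.30).
* Additive white Gaussian noise per channel (`noise_sd`, default 0).

It does **not** emulate heart-rate variability, sensor contact artifacts,
ambient noise spectra, wheeze/crackle morphology, or any absolute
calibration to mL. Passing the recovery experiments therefore shows that
the pipeline correctly extracts what the generator encodes — monotone
sound-energy/volume coupling, RSA phase structure, cough transients — not
that it would achieve the same separation on clinical recordings. Note also
that the simulator ties RSA depth to a constant, not to tidal volume, so
the ECG channel alone does not discriminate volumes in simulation; the
discrimination burden falls on the sound channel, and the ECG axis of the
signature matrix mainly encodes within-cycle timing.

## Problem sizes and defaults

The recovery experiment (`recovery_study()`) simulates 10 cycles per
condition (500/750/1000 mL and cough; 40 s per condition at 4 kHz), builds
templates from the first five cycles of each and classifies the remaining
twenty held-out cycles; the 1000 vs 500 mL F test uses five cycles per
group, df = (1, 8). Monte-Carlo calibration of the F test uses 10⁴
replicates of two five-sample standard-normal groups. These sizes keep the
whole suite comfortably interactive while leaving the statistics
well-resolved.

## Known limitations

* Cycle boundaries must be known (paced protocol or annotations).
* Tertile zone boundaries need variation in the pooled cumulative values;
  constant input is rejected rather than silently zoned.
* AUCs are relative; no mL calibration is attempted or claimed.
* Classification quality depends on the template conditions spanning the
  targets; the library stores its boundaries precisely so that this
  coupling is explicit.
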