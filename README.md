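# respsig

Breathing-pattern analysis from a two-channel wearable chest sensor: lung
sound plus electrocardiogram (ECG), both sampled at 4 kHz. The package is
aimed at researchers prototyping respiratory-monitoring pipelines — detecting
shallow breathing and coughing, and tracking tidal-volume changes — without
access to spirometry.

## Method

For each breathing cycle (4 s: 2 s inhale, 2 s exhale) and each channel:

1. **Band split.** The sound channel is filtered into a low (< 2 Hz, chest
   motion) and a high (> 150 Hz, breath sound) band; the ECG channel into
   < 150 Hz (cardiac) and > 150 Hz bands. Filters are 4th-order Butterworth
   applied forward–backward (zero phase), so envelopes stay aligned with the
   cycle annotations.
2. **Energy envelope.** The moving variance over a 250 ms window
   (1000 samples at 4 kHz) turns the filtered signal into a nonnegative
   energy envelope.
3. **Polynomial AUC.** A 7th-order polynomial is fitted to the envelope of
   each cycle on a normalized time axis, and integrated analytically (with
   negative excursions clipped to zero) into an area under the curve (AUC).
   The within-cycle cumulative AUC and its increments act as a lung-volume
   proxy: deeper breaths give larger sound-band AUCs.
4. **Signature matrices.** The cumulative-AUC curves of the two channels are
   sampled at 40 points per cycle (100 frames/s of raw signal at 4 kHz) and
   each point is assigned to one of three zones (lower/middle/upper,
   tertile boundaries by default). The joint counts form a 3×3 probability
   map `SIG_k` with entries

   `sig_ij = P(sound value in zone j ∩ ECG value in zone i)`,

   rows indexed by the ECG zone and columns by the sound zone.
5. **Template classification.** A target matrix is compared to stored
   condition templates by the sum of squared element differences
   `E = Σ_ij (sig_ij^T − sig_ij)²` and assigned the label of the nearest
   template.
6. **Group statistics.** Per-cycle cumulative AUCs are compared between
   conditions (e.g. 1000 mL vs 500 mL tidal volume) with a classical
   two-group one-way ANOVA: F value, p value, and the upper-α F critical
   value (5.318 at α = 0.05 with five cycles per group).

A seedable simulator generates recordings with the structure the method
assumes — tidal-volume-dependent inhalation sound bursts, respiratory
amplitude modulation of ECG beats (beat heights drop during inhalation),
cough transients — so the full chain runs without any measured data.

## Worked example

```r
library(respsig)

rec <- simulate_recording(sim_config(n_cycles = 5, tidal_volume_ml = 1000, seed = 1))
rec
#> <multimodal_recording> 80000 samples/channel @ 4000 Hz (20.0 s), 5 cycles (0 cough)

round(extract_cycle_features(rec, "sound")$auc, 3)
#> [1] 1.631 1.629 1.648 1.635 1.634

st <- recovery_study(seed = 1)   # 10 cycles each of 500/750/1000 mL + cough
round(st$mean_auc, 2)
#>  500mL  750mL 1000mL  cough
#>   0.41   0.92   1.63   4.16
st$f_sound
#> <group_comparison> 1000 mL (n=5) vs 500 mL (n=5): F(1,8) = 2.386e+05,
#>   p = 3.453e-19 (critical 5.318 at alpha=0.05)
st$accuracy
#> [1] 1
```

The per-cycle sound AUCs track tidal volume (deep breathing ≈ 4× the
shallow-breathing AUC, coughing larger still), the 1000 vs 500 mL F value
far exceeds the 5.318 critical value, and every held-out cycle is assigned
to its true condition by signature-matrix classification.

The same stages are available from the shell via
`inst/cli/respsig.R` (`simulate`, `features`, `templates`, `fuse`,
`classify`, `stats` subcommands).

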