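# cionaphase

Burst detection, circular phase locking and tail kinematics for
dual-channel calcium imaging of the bilateral MN2 motor-neuron pair in
developing *Ciona* larvae.

## The problem

A single pair of motor neurons (MN2L / MN2R) paces the early motor
behavior of *Ciona*. Across development their spontaneous Ca²⁺ bursts
move through seven recognizable regimes: sporadic and independent on the
two sides (I), converging onto a regular ~40 s rhythm (II–III),
intermittently (IV) and then fully (V) synchronized left–right at ~55 s,
interval-lengthened to ~85 s with occasional long (>30 s) bursts (VI),
and finally sporadic-but-synchronized during tail absorption (VII).
Quantifying this requires four analyses that this package implements as
a single reproducible pipeline for anyone studying bilateral oscillator
development in calcium-imaging data:

* **Burst detection** on ΔF/F₀ traces: rolling-percentile normalization,
  Savitzky–Golay denoised differentiation, peak detection at a robust
  (MAD-based) prominence threshold, and the derivative zero-crossing
  duration rule (onset = rise from 0 before the peak, offset = return to
  0 after the post-peak negative lobe).
* **Cycle-anchored phase locking**: each left burst gets an angle
  `360·(t − tᵢ)/(tᵢ₊₁ − tᵢ)` within its enclosing right-channel cycle,
  wrapped to (−180°, 180°]; concentration is measured by the mean
  resultant length `R = |Σe^{iθ}|/n` with the classical Rayleigh
  p-value `p = exp(√(1+4n+4(n²−Rn²)) − (1+2n))`.
* **Seven-phase classification** of sliding windows by interval CV,
  synchrony fraction and interval-lengthening ratio, with explicit,
  config-exposed thresholds.
* **Tail kinematics**: signed Menger curvature
  `κ = 4·Area(ABC)/(|AB||BC||CA|)` and bending angle from three tracked
  body parts (DeepLabCut CSV dialect), bout segmentation into left/right
  early tail flicks versus swimming, and zero-crossing beat frequency.

Because the original recordings are not deposited, a synthetic-data
module (`phase_defaults()`, `sample_event_trains()`, `render_trace()`,
`simulate_tail()`, `simulate_cohort()`) generates two-channel traces,
pose tracks and cohort tables with known ground truth; the whole test
suite runs against it.

## Worked example

Simulate a recording that passes through intermittent synchrony (IV),
full synchrony (V) and the lengthened-interval regime (VI), then analyze
it end to end:

```r
library(cionaphase)

plan <- data.frame(phase      = c("IV", "V", "VI"),
                   duration_s = c(1200, 1650, 2550))
sim <- simulate_recording(plan, seed = 42)
rep <- analyze_recording(sim$trace,
                         config = run_config(monotone_segments = TRUE))

rep$trains$R
#> <burst_train> channel R - 89 events, mean interval 60.4 s

rep$circular
#> <circular_phase_result> n = 88, mean = -3.1 deg, R = 0.764, p = 1.42e-27

rep$segments[, c("label", "t_start", "t_end", "mean_interval_s",
                 "cv", "sync_fraction")]
#>   label t_start  t_end mean_interval_s        cv sync_fraction
#> 1    IV    38.4  984.6        40.30333 0.1276433     0.3939394
#> 2     V   984.6 2787.6        56.76353 0.1696860     0.8930481
#> 3    VI  2787.6 5351.4        86.33091 0.1419386     0.9256198
```

Reading the output: the detector found 89 right-channel bursts; the
pooled phase-locking across the whole recording is moderately
concentrated (R = 0.76 — the unsynchronized phase-IV stretch dilutes the
tightly locked V/VI angles, whose per-segment R values in
`rep$segment_circular` exceed 0.9); and the classifier recovers the
three regimes with their interval means (40 / 57 / 86 s) and synchrony
fractions (0.39 / 0.89 / 0.93). `write_results()` exports events,
window features, segments and a schema-versioned JSON summary;
`read_trace_csv()` / `read_dlc_csv()` ingest external trace and pose
data.

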