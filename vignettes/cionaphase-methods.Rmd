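---
title: "Quantifying developing bilateral motor-neuron activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developing bilateral motor-neuron activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cionaphase)
```

## The scientific problem

In *Ciona* larvae, a single pair of cholinergic motor neurons (MN2L/MN2R,
the A10.64 pair) sets the rhythm of early motor behavior. Over development
(roughly stages St.22 to St.34) their spontaneous Ca^2+^ activity changes
from sporadic and independent on the two sides, through increasingly
regular oscillation at a ~40 s inter-burst interval, to full left–right
synchronization at ~55 s intervals in swimming larvae, then to lengthened
(~85 s) and finally again sporadic — but still synchronized — rhythms
during tail absorption. This trajectory is commonly summarized as seven
phases, I–VII, defined by two features of the bilateral burst trains:
interval regularity and left–right synchrony.

`cionaphase` turns that qualitative account into a reproducible pipeline:

1. **Burst detection** on two-channel ΔF/F~0~ traces via a denoised
   (Savitzky–Golay) derivative;
2. **Cycle-anchored phase locking**: each left-channel burst is assigned
   an angle within its enclosing right-channel cycle (0° at one right
   peak, 360° at the next) and the concentration of these angles is
   tested with the Rayleigh statistic;
3. **Rule-based seven-phase classification** over sliding windows of the
   two burst trains;
4. **Tail kinematics**: three-point midline curvature, signed bending
   angle from pose-tracked coordinates, bout segmentation into early tail
   flicks (lETF/rETF) versus swimming, and beat-frequency estimation;
5. **Cohort statistics**: onset-laterality dominance and
   photostimulation-response tabulation.

Because the underlying recordings are not publicly deposited, the package
ships a **synthetic-data generator** that emulates their statistical
structure with known ground truth; every claim the test suite makes about
the pipeline is a claim about recovery of that ground truth.

## The synthetic generator

### Event trains

The right channel is a gamma renewal process: intervals have the phase's
mean (40 / 55 / 85 s across the regimes) and a coefficient of variation
that encodes "sporadic" (CV 0.7–0.8), "converging" (0.35) or "regular"
(0.12) rhythms. The gamma family was chosen for positivity and a directly
tunable CV; the source material states only means and qualitative
dispersion, so the CV values are package defaults. Left–right coupling is
a per-event Bernoulli: with probability `coupling_prob` a right event
spawns a left partner jittered by *N*(0, 0.5 s); the remaining left
activity is an independent renewal process thinned so the left marginal
rate matches the right. Coupling 0 models phases I–III, 0.5 the
intermittent synchrony of phase IV, and 1 the synchronized phases V–VII.
Event durations are drawn uniformly from 3–8 s, except *long bursts*
(probability 0.15 in phases VI–VII) drawn from 31–45 s; a duration is
capped at 80% of the gap to the next event so ground truth stays
resolvable. The 30 s long-burst threshold is fixed.

### Fluorescence read-out

Ordinary bursts render as double-exponential transients
$A\,(1 - e^{-s/\tau_r})\,e^{-k_{off} s}$, normalized so that $A$ is the
peak ΔF/F~0~; long bursts hold a saturating rise (with a 15% droop across
the plateau, as sustained Ca^2+^ bursts droop in practice) for the drawn
duration and then decay at $k_{off}$. The decay rate is the indicator's
off-rate: 1.1 s^-1^ for a GCaMP6s-like read-out (decay time constant
~0.91 s) and 3.9 s^-1^ for GCaMP6f; the bare literature numbers are
interpreted as s^-1^, consistent with the indicator kinetics literature.
Contributions sum, Gaussian noise of SD 0.05 ΔF/F~0~ is added, and the
trace is expressed as raw intensity `baseline * (1 + signal + noise)` at
a 0.2 s frame interval — the slow-imaging rate at which bilateral
recordings are practical. Rise time (0.5 s), amplitude (mean 1.0, CV
0.1), noise SD and baseline are invented package defaults, documented
here because no measured values exist to copy; the rise time was chosen
by simulation so that the derivative-based detector operates at a
realistic signal-to-noise ratio (about 7:1 on the smoothed derivative).

What the generator does **not** emulate: within-burst spiking
substructure (the notched fast-indicator transients), photobleaching,
movement artifacts, focus drift, or cross-channel optical bleed-through.
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness under its stated noise model, not robustness to
every pathology of real microscopy.

### Tail tracks and cohorts

`simulate_tail()` renders a bending-angle time course from a bout plan —
half-sine single-signed excursions for early tail flicks (30°), tapered
sinusoids for swim bouts (25°, at the per-phase frequencies 4.3 / 7.2 /
9.7 / 10 Hz when emulating specific stages) — and converts it into
coordinates of the three tracked body parts (ocellus, mid-tail, tail
tip) with 0.3 px tracking noise. `simulate_cohort()` draws per-embryo
first-onset sides with a default right-first probability of 13/17,
matching the observed right-dominant cohort (76%).

## Burst detection

The trace is normalized per channel to ΔF/F~0~ with a rolling
20th-percentile baseline (window 120 s — longer than the longest
inter-burst interval, so the baseline tracks drift but not bursts;
evaluated on a stride of 1/20 window and interpolated). The normalized
trace is differenced, scaled to per-second units, and smoothed with a
Savitzky–Golay filter (window 7 frames = 1.4 s, order 3; both exposed in
the configuration — the source pipeline does not state its values).

Candidate peaks are local maxima of this denoised derivative whose
height **and** topographic prominence exceed `prominence_k = 4` robust
noise scales (MAD). Height is required in addition to prominence because
the prominence of the tallest noise peak spans the full data range and
would fire on any pure-noise trace. Each accepted peak expands to an
event by the duration rule: the onset is where the derivative last rose
from 0 before the peak, and the offset is where it climbs back to 0
after the negative lobe that follows the fluorescence maximum. Zero
crossings use a hysteresis band of ±0.1 noise scales (floored at 0.1% of
the derivative range so that noiseless traces terminate), the negative
lobe must reach 2 noise scales, and a lobe only ends the event if the
smoothed trace has actually fallen below onset + 33% of the peak
elevation — a sub-threshold noise dip on a long-burst plateau must not
truncate the burst. Peaks closer than `min_separation = 2 s` merge,
keeping the larger peak, the earlier onset and the later offset. Events
touching the recording boundary are kept but flagged truncated.

**Peak time.** Whether "peak" means the derivative maximum or the
fluorescence maximum is genuinely ambiguous in derivative-based
pipelines. We anchor `peak_s` at the fluorescence maximum between onset
and offset, located as the *first entry of the SG-smoothed trace into
the peak band* (within 2 robust noise scales of the window maximum). On
noiseless data this is the argmax; on noisy plateau-shaped bursts a raw
argmax is uniformly scattered across the plateau, which would corrupt
both interval CVs and left–right synchrony matching, while the
band-entry time is stable to within a few frames. Intervals are
consecutive `peak_s` differences; their sum telescopes exactly to the
peak span.

## Phase locking

Left peaks falling in the half-open cycle $[t_i, t_{i+1})$ between
consecutive right peaks map to $360(t - t_i)/(t_{i+1} - t_i)$ degrees,
wrapped to the signed interval (−180°, 180°] — signed because
synchronized regimes cluster near 0° and small negative means are
meaningful. A left peak exactly at a right peak belongs to the cycle it
starts (0°). Peaks before the first or after the last right peak are
discarded and counted. The Rayleigh statistic is
$R = \lvert\sum e^{i\theta}\rvert / n$ with the classical small-sample
p-value approximation
$p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\big)$,
$R_n = nR$ — the convention of the standard circular-statistics
toolboxes. Pooling angles across recordings is plain concatenation, with
no per-animal weighting. The test suite verifies the closed forms
($R = 1$ for identical angles, $R = 0$ for equally spaced angles,
$R = \sqrt{2}/2$ for {0°, 90°}), rotation invariance, and a 5% ± 2%
empirical type-I error under the uniform null at $n = 100$ over 2000
replicates.

## Seven-phase classification

Features are computed over sliding windows of 10 right-channel cycles,
stepped by 2 cycles: per-channel interval means and CVs, the synchrony
fraction (greedy nearest-neighbour matching of peak times within
`max(2 s, 5% of the window's median right interval)`, each burst matched
at most once, normalized by right-burst count), the long-burst count,
and the ratio of the window's mean right interval to a reference
synchronized-regime interval.

The decision list, evaluated in order with first match winning, uses
thresholds `cv_regular = 0.25`, `cv_sporadic = 0.5`, `s_lo = 0.2`,
`s_hi = 0.8`, `r_long = 1.3`:

| label | rule |
|-------|------|
| VII | sync ≥ 0.8 and CV > 0.5 |
| VI  | sync ≥ 0.8, CV ≤ 0.25, interval ratio ≥ 1.3 |
| V   | sync ≥ 0.8 and CV ≤ 0.25 |
| IV  | CV ≤ 0.25 and 0.2 < sync < 0.8 |
| III | CV ≤ 0.25 and sync ≤ 0.2 |
| II  | 0.25 < CV ≤ 0.5 |
| I   | CV > 0.5 |

The source taxonomy is qualitative; these cut-points are explicit
package definitions chosen to separate the printed regimes with margin
(the 55 → 85 s lengthening gives a ratio of ~1.55 against `r_long` 1.3;
"rarely synchronizes" sits well inside (0.2, 0.8)). The regularity
feature is the right-channel CV — the right channel anchors the cycle
analysis, and under intermittent coupling the left train is a
superposition whose CV is inflated for reasons unrelated to rhythm
regularity. The reference interval is the median right interval over the
first **three consecutive** fully synchronized windows; requiring a
sustained run matters because a single chance-synchronized window in the
40 s regime would otherwise make genuine 55 s phase-V windows look
"lengthened". Recordings that begin after synchronization was
established should pass `ref_interval` explicitly.

Two honest limitations, by design: phase II is defined in the source by
a *trend* (intervals beginning to converge), which a stationary window
cannot capture — we approximate it by intermediate dispersion; and
independent same-frequency oscillators (phase III) drift slowly in
relative phase, so individual windows can transiently look
"synchronized" by chance — classification is therefore evaluated on
modal window labels, and segment smoothing (width-3 mode filter, with an
optional monotone projection onto the developmental order) cleans
isolated blips. Developmental stage metadata never enters the
classifier.

## Kinematics

Three-point curvature is the Menger curvature
$\kappa = 4\,\mathrm{Area}(ABC)/(\lvert AB\rvert\,\lvert BC\rvert\,\lvert CA\rvert)$
— equivalently $2\sin\angle B / \lvert AC \rvert$, the reciprocal
circumradius — signed by the z-component of the cross product at the
mid-tail point; the bending angle is 180° minus the interior angle at
the mid-tail point, signed the same way. Left bends are positive by
package convention (the source plots left/right without a stated sign).
Both reduce the midline to its start, middle and end points, matching
the three tracked body parts; pose frames with any part below the 0.9
likelihood threshold are excluded.

Movement epochs are runs where the absolute bending signal exceeds
`max(3 × MAD of the quiescent baseline, 3°)` — quiescence is estimated
in a first pass as frames below the absolute floor, so that long bouts
cannot inflate their own threshold — for at least 50 ms, after bridging
sub-threshold gaps shorter than 0.2 s (an alternating bout crosses zero
twice per cycle and must not be split there). An epoch with at least 3
hysteresis sign reversals at ≥ 3 Hz is a swim bout; other epochs are
early tail flicks, sided by their extreme deflection. Beat frequency
uses hysteresis zero crossings rather than spectral peaks — robust for
the 1–30 s bouts involved: with reversals at $t_1 \ldots t_k$, the
frequency is $(k-1) / (2(t_k - t_1))$ Hz. Burst–bout co-occurrence
assigns each bout to the burst windows it overlaps (±2 s) per channel,
tabulating lETF/rETF/swim against L-only/R-only/both/neither.

## Reproducibility and problem sizes

All samplers take explicit seeds and restore the caller's RNG state;
identical seeds give byte-identical outputs. The test suite and the
acceptance script run single-phase recordings of 25–55 cycles
(2 000–4 600 s at 0.2 s/frame), seven-phase staged recordings of 50
cycles per phase for classification accuracy, 200 pure-noise traces of
100 s for the false-positive rate, 2 000 Monte-Carlo replicates for the
Rayleigh type-I error, and 1 000 random triangles against an independent
circumradius-solving oracle for curvature (agreement to 1 part in 10^9^).
These sizes give stable statistics while keeping a full run in well
under a minute on one core.

## Known limitations

* Thresholds separating "sporadic" from "regular" and "rarely" from
  "fully" synchronized are package definitions, not measured facts; they
  are all exposed in `run_config()` / `phase_thresholds()`.
* The detector's duration estimates include the indicator decay tail, so
  durations are biased upward by a few seconds relative to the
  underlying neural event; the 30 s long-burst classification is robust
  to this.
* The sign convention for left/right bends is explicit but cannot be
  validated against the source, which does not state one.
* Phase classification assumes the right channel is present and
  rhythmogenic; recordings where the left channel leads are analyzable
  (cycle anchoring is a convention), but the channel roles are not
  auto-detected.
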