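---
title: "Quantifying the pupillary light reflex from B-mode ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pupillary light reflex from B-mode ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonopupil)
```

## The measurement problem

The pupillary light reflex (PLR) — constriction of the pupil after a light
stimulus, followed by partial redilation — is a core brainstem-function
indicator in neurocritical care. Infrared pupillometry (IPA) measures it
optically on the open eye, but is unusable when eyelid edema, dressings or
orbital trauma block optical access. Transpalpebral B-mode ultrasound can
image the pupil through the closed eyelid: in a tangential probe
orientation the pupil appears as an anechoic (dark) gap in the bright iris
echo band, and its width tracks the pupil diameter. Automated ultrasound
pupillometry (Auto-UPA) segments that gap frame by frame in a cine loop
and derives the standard PLR metrics from the diameter–time curve.

`sonopupil` implements this measurement chain end to end, together with
the paired method-comparison and reliability statistics used to validate
one pupillometry modality against another, and a synthetic cine generator
with analytically known ground truth so that every stage can be tested
against an exact oracle.

## The PLR waveform model

The generator's ground truth is a four-phase diameter–time model
\(d(t)\): a constant baseline \(d_0\) (INIT); after the stimulus at
\(t_s\) and a latency \(\ell\) (LAT), a constriction phase of duration
\(c\) down to the minimum \(d_{\min}\) (END); a recovery phase of
duration \(r\) regaining a fraction \(\rho \in [0,1]\) of the
constriction amplitude \(A = d_0 - d_{\min}\); and a terminal plateau.
Segments are linear by default; an exponential mode uses normalised
exponential segments
\(\bigl(e^{-t/\tau} - e^{-T/\tau}\bigr)/\bigl(1 - e^{-T/\tau}\bigr)\)
so the phase endpoints are attained *exactly* — this keeps the
closed-form metrics valid in both modes:

\[
\mathrm{DELTA} = \frac{A}{d_0},\qquad
\mathrm{ACV} = \frac{A}{c},\qquad
\mathrm{ADV} = \frac{\rho A}{r},
\]

with ACV and ADV defined as endpoint secants over their phase windows.
`true_metrics()` returns these without any simulation, which is what
makes parameter-recovery testing well posed.

## What the synthetic scenes emulate — and what they do not

Each frame is a deterministic tissue template — a bright eyelid band at
the top, a bright iris band centred on the pupil row, an anechoic gap of
width \(d(t)\) — multiplied by gamma-distributed speckle of mean 1
(shape 4 by default; smaller is noisier; `Inf` disables noise), then
convolved with a Gaussian point-spread function (σ = 1 px) and clipped to
\([0,1]\). Multiplicative gamma speckle is the standard cheap surrogate
for fully developed ultrasound speckle: it stresses thresholding and
morphology realistically at desk scale without RF-level beam simulation.

The default scene is 96×128 px at 0.1 mm/px, 30 Hz, 5 s, stimulus at
1.0 s — pupil diameters of 2–6 mm span the frame comfortably. Acquisition
frame rate and spatial resolution of clinical devices are typically not
published, so these are deliberate implementation choices, exposed in
`scene_config()`.

Not emulated: physically realistic beamforming, depth-dependent
attenuation, eye or probe motion, blinks, 3-D pupil geometry, consensual
(contralateral) responses. Passing tests on these scenes therefore
demonstrate the correctness of the *algorithmic chain* under controlled
speckle and blur — they do not certify performance on clinical images,
where motion and shadowing are the dominant failure modes.

## Segmentation: thresholding, morphology, tracking, chord

`segment_frame()` realises the four-stage pipeline:

1. **Intensity thresholding** of dark pixels. The default is Otsu's
   method restricted to the iris-band region of interest: a whole-frame
   Otsu cut first separates echogenic tissue from dark pixels; the band
   is the set of rows dominated by bright tissue; a second Otsu over band
   pixels then splits iris echo from the anechoic gap. A fixed threshold
   is available for deterministic fixtures.
2. **Morphological filtering**: binary opening then closing with a 3×3
   box applied radius-many times (defaults 1 and 1), then rejection of
   components below 20 px. "Edge detection" is realised as the boundary
   of this filtered component — the measured quantity is a horizontal
   run length, so sub-pixel contour refinement is deliberately out of
   scope. An optional running-median smoothing of the per-row boundary
   extents is provided (off by default).
3. **Component tracking**: the component whose centroid is nearest the
   previous frame's centroid is selected (largest first when no prior;
   ties broken by larger area, then smaller row index — determinism
   matters for reproducible traces). A component farther than the
   tracking search radius (20 px) is rejected, and the frame is marked
   invalid rather than mistracked.
4. **Chord measurement**: the pupil diameter is the maximal contiguous
   run of pupil pixels on the mask row nearest the component centroid,
   measured inclusively (`max_col − min_col + 1` pixels) and scaled by
   the pixel spacing. The run *through the centroid row* is used rather
   than the maximum over all rows; both readings of "maximal horizontal
   chord through the pupil centroid" are defensible, and the centroid-row
   variant is the implemented default.

Degenerate frames (all bright, empty, blanked) yield `valid = FALSE`
entries in the trace, never errors; downstream metric extraction and
quality control treat validity explicitly.

Performance note: morphology is implemented as vectorised shift-and
erosion/dilation and the blur as a separable banded-matrix product
(numerically identical to a truncated Gaussian kernel), keeping the full
render-and-segment cycle under ~5 ms per frame so that grid-scale
property tests run at realistic sizes.

## Metric extraction and its operational choices

The clinical definitions of the six metrics leave the onset rule, the
baseline estimator and the velocity windows unspecified, and commercial
devices do not publish theirs. `compute_metrics()` makes these choices
explicit and configurable (`metrics_config()`):

* the valid-frame trace is smoothed with a **moving median** (window 5
  frames) — robust to single-frame segmentation glitches;
* **INIT** is the mean smoothed diameter over the 0.8 s pre-stimulus
  baseline window;
* **onset of constriction** is the first post-stimulus sample below
  `INIT − max(3·σ_baseline, 0.05 mm)` that keeps non-increasing for 3
  frames; the onset time is then refined to the continuous-time
  threshold crossing by linear interpolation between the bracketing
  samples, which halves the frame-quantisation delay. **LAT** is onset
  minus stimulus onset;
* **END** is the minimum smoothed diameter after onset (earliest sample
  on ties), **DELTA** the constriction ratio, **ACV** the secant
  `(INIT − END)/(t_min − onset)`, and **ADV** the secant from the
  minimum to the earliest recovery of 50% of the constriction amplitude
  (falling back to the last valid frame when that level is never
  regained).

Three systematic effects of these rules are worth knowing, because they
set the accuracy floor of any device built on integer-pixel chords:

1. The threshold-crossing onset is *late* by about
   `max(3σ, 0.05 mm)/ACV` (≈ 0.03–0.09 s at realistic velocities), so
   LAT carries a positive offset and the ACV window is shortened on the
   left. This is a calibration difference, not noise: two devices with
   different onset rules will show a systematic latency bias of exactly
   this kind, which is why the study emulator applies the *same*
   extraction operator to both emulated modalities.
2. Chord quantisation at 0.1 mm/px makes the trace touch its minimum
   plateau about `0.05 mm/ACV` early, shortening the ACV window on the
   right. Together with (1), the relative ACV overestimate is roughly
   `(drop + pixel/2)/A` — about 10% at a 1 mm constriction amplitude.
   Dynamic indices are genuinely more fragile than diameters at these
   resolutions.
3. The window-5 median clips the constriction vertex by roughly
   `ACV/frame_rate` mm, biasing END slightly high (and DELTA slightly
   low). At 30 Hz and typical velocities this is 0.03–0.05 mm. A side
   effect: if the generator's recovery fraction equals the ADV recovery
   target exactly, the (clipped) target can sit just above the attained
   plateau and the ADV secant falls back to the last frame — the
   generator default (60% recovery vs a 50% target) leaves headroom on
   purpose.

Triplicate acquisitions are averaged arithmetically field-wise over
defined values (`average_session()`); a field is undefined in the average
only when undefined in all acquisitions, and the averaged DELTA is
recomputed from the averaged INIT and END so the constriction-ratio
identity holds exactly in every exported record. Quality control
(`quality_control()`) fails a trace with named reasons when fewer than
80% of frames are valid, the baseline coefficient of variation exceeds
0.05, the recording ends less than 1 s after the stimulus, or fewer than
3 valid baseline frames exist.

## The agreement and reliability battery

Paired eye-level comparison of two modalities (`compare_modalities()`)
uses the session-averaged values and reports, per metric:

* **Bland–Altman**: bias = mean(a − b), SD of differences with the n−1
  denominator, limits of agreement `bias ± 1.96·SD` — the 1.96 normal
  multiplier, with no small-sample t correction, matching the reporting
  convention of the clinical literature this mirrors;
* **OLS regression** of the ultrasound value on the infrared value
  (slope, intercept, R²) and **Pearson r** with the Fisher-z interval
  `tanh(atanh r ± z_{0.975}/√(n−3))`, degenerate at |r| = 1;
* **proportional bias**: OLS of the differences on the within-pair
  means with a two-sided t-test on n − 2 df; exact zero-residual cases
  are resolved analytically (zero slope ⇒ p = 1).

Reliability uses single-measure intraclass correlations computed from the
explicit two-way sums-of-squares decomposition: ICC(2,1) (two-way random
effects, absolute agreement) for inter-observer designs — sensitive to
systematic shifts between observers — and ICC(3,1) (two-way mixed
effects, consistency) for intra-observer repeats. The implementation is
cross-checked in the test suite against an independent `aov()`-based
mean-squares route to 1e-10. Shapiro–Wilk normality screening delegates
to `stats::shapiro.test` — the Royston approximation is not this
package's contribution — returning `NA` for degenerate constant samples.
No multiple-testing correction is applied, and eyes are treated as
independent observations (no within-patient clustering adjustment),
matching the reporting conventions this battery reproduces; both are
stated limitations rather than recommendations.

## The study emulator

`run_study()` composes everything into a reproducible paired study: one
waveform per eye drawn from a configurable population (defaults follow
the infrared reference summary shipped in
`inst/extdata/icu_agreement_summary.csv`: baseline 4.05 ± 0.57 mm,
constriction ratio 0.252 ± 0.052, latency 0.278 ± 0.027 s, velocities
1.461 ± 0.297 and 0.776 ± 0.173 mm/s, truncated at physiologic bounds;
phase durations derived from the drawn velocities and clamped so the
response completes within the 5 s recording); triplicate ultrasound
acquisitions rendered, segmented, quality-controlled, derived and
averaged per eye; and a paired infrared modality emulated by applying
the *same* `compute_metrics()` operator to a noise-free analytic trace
at the device frame rate, then adding configurable per-metric
calibration offsets and Gaussian measurement noise. Sharing the
extraction operator is deliberate: real infrared devices also run an
onset-detection rule, so the detection delay largely cancels in the
paired difference and an injected calibration offset is recovered as the
reported bias — which is exactly how between-device latency biases arise
in practice.

Two-observer reliability is emulated by re-acquiring each eye with
observer-specific probe-placement jitter (pupil-centre shifts of up to
±2 px) and independent speckle, giving ICC < 1 structure; intra-observer
repeatability uses the first observer's three repetitions. All
randomness derives from one master seed, and identical configuration and
seed produce byte-identical CSV reports (numbers are written in fixed
"g" format to be locale- and platform-stable). A manifest JSON records
the seed and an MD5 hash of the serialised configuration.

## Numerical and degenerate-input choices

* Rendering with `speckle_shape = Inf` is exactly noise-free and
  bit-reproducible; the same seed always yields identical frames, and
  the generator restores the caller's RNG state.
* Pixel indices are 1-based (row 1 = top, column 1 = left); gap widths
  are rounded to the nearest pixel count, so the noise-free rendered
  width is within half a pixel of the analytic diameter.
* A pupil wider than the frame is a configuration error at render time;
  an empty, all-bright or blanked frame is an invalid mask, never an
  exception.
* `bland_altman` requires n ≥ 2; regression-based operations require
  n ≥ 4 and non-zero variance; ICC requires a complete matrix (no
  imputation).
* Differences identical up to floating-point rounding short-circuit the
  proportional-bias test to slope 0, p = 1.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise: a 3×3×3 waveform grid
(population mean ± 1 SD on baseline, constriction ratio and latency;
phase durations from the population mean velocities) — noise-free for
the segmentation oracle and with 20 speckle seeds per waveform (5 in the
acceptance script) for parameter recovery; 100 random subjects×raters
tables for the ICC oracle; 500 bivariate-normal draws for Fisher-z
coverage; and a 20-patient, 40-eye, triplicate, two-observer study for
end-to-end offset recovery and reliability. These sizes were chosen to
estimate medians and coverages stably at desk scale.

## Known limitations

* Integer-pixel chords at 0.1 mm/px bound the accuracy of the dynamic
  indices as analysed above; ACV is the most affected metric, and a
  relative error near 10% at 1 mm amplitudes is structural, not a bug.
* The onset rule's latency offset means absolute LAT values are
  device-convention-specific; between-device latency comparisons are
  only meaningful when both conventions are known.
* The speckle model has no spatial correlation beyond the blur kernel
  and no depth dependence; segmentation robustness on clinical loops
  with motion, shadowing or low gain is untested by design.
* ICC confidence intervals are not implemented (point estimates and
  their ANOVA mean squares are reported).
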