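# sonopupil

Automated ultrasound pupillometry in R: simulation, segmentation, and
the full agreement/reliability statistics for paired pupillometry
studies.

## The problem

The pupillary light reflex (PLR) — pupil constriction after a light
stimulus, followed by redilation — is a standard brainstem-function
indicator in intensive care. Infrared pupillometers measure it optically
on the open eye, but fail when eyelid edema, dressings or orbital trauma
block optical access. Transpalpebral B-mode ultrasound images the pupil
through the closed eyelid: in a tangential view the pupil appears as an
anechoic gap in the bright iris echo band, and the gap width tracks the
pupil diameter. `sonopupil` is for researchers developing or validating
this kind of automated ultrasound pupillometry: it implements the whole
measurement chain and the statistical battery used to compare it against
a reference modality, plus a synthetic cine generator with exact ground
truth so every stage is testable against an oracle.

## What it computes

From a diameter–time curve d(t) with baseline d0, minimum d_min,
amplitude A = d0 − d_min, latency ℓ, constriction duration c and
recovery of a fraction ρ of A over duration r, the six standard PLR
metrics are

    INIT = d0          END = d_min        DELTA = A / d0
    LAT  = ℓ           ACV  = A / c       ADV   = ρ·A / r

with ACV/ADV as endpoint secants over their phase windows. The pipeline:

* **synthesis** — parametric PLR waveform (piecewise-linear or
  exponential) rendered into multi-page B-mode cine loops with gamma
  speckle and Gaussian blur; closed-form `true_metrics()`.
* **segmentation** — per-frame Otsu thresholding restricted to the iris
  band, binary opening/closing, component tracking across frames, and
  the maximal horizontal chord through the pupil centroid.
* **plr_metrics** — moving-median smoothing, baseline estimation,
  k·σ onset detection with persistence, the six metrics, triplicate
  averaging, and named quality-control checks.
* **agreement_reliability** — Bland–Altman bias and 95% limits of
  agreement, OLS regression, Pearson r with Fisher-z CI,
  proportional-bias regression, ICC(2,1)/ICC(3,1) from explicit two-way
  sums of squares, Shapiro–Wilk screening.
* **pipeline** — `run_study()` emulates a complete paired two-modality,
  two-observer eye-level study with one master seed and byte-identical
  reports; `inst/cli/sonopupil.R` exposes the stages as a command-line
  tool (`simulate`, `segment`, `metrics`, `compare`, `reliability`,
  `run-study`, `init-config`).

## Worked example

```r
library(sonopupil)

# ground-truth waveform: 4.0 -> 3.0 mm, 0.3 s latency, 1 s constriction,
# 60% recovery over 1.2 s
w <- plr_waveform(baseline_diameter = 4.0, min_diameter = 3.0,
                  latency = 0.3, constriction_duration = 1.0,
                  recovery_fraction = 0.6, recovery_duration = 1.2)
true_metrics(w)
#> PLR metrics:
#>   INIT 4.000 mm  END 3.000 mm  DELTA 0.250
#>   LAT 0.300 s  ACV 1.000 mm/s  ADV 0.500 mm/s

# render a speckled cine loop and measure it back
r  <- render_cine(w, scene_config(rng_seed = 42))
r$loop
#> Cine loop 'synthetic': 150 frames of 96x128 px, 30 Hz, 0.1 mm/px, stimulus at 1 s
tr <- extract_trace(r$loop)
tr
#> Diameter trace 'synthetic': 150 frames, 100% valid, stimulus at 1 s
compute_metrics(tr)
#> PLR metrics:
#>   INIT 4.000 mm  END 3.000 mm  DELTA 0.250
#>   LAT 0.350 s  ACV 1.053 mm/s  ADV 0.536 mm/s
```

The measured INIT/END/DELTA match the ground truth at the 0.1 mm/px
pixel resolution. LAT reads 0.05 s late — the onset rule fires when the
smoothed trace has dropped 0.05 mm below baseline, a calibration offset
every threshold-based device shares — and ACV is correspondingly ~5%
high. The methods vignette derives these floors.

Reliability of repeated measurements:

```r
x <- cbind(c(4.1, 3.9, 4.4, 3.6, 4.0, 4.3),   # observer 1, 6 eyes
           c(4.2, 4.0, 4.5, 3.7, 4.1, 4.4))   # observer 2 (+0.1 shift)
icc(x, "icc_2_1")
#> ICC(2,1) two-way random, absolute agreement: 0.9432  (n = 6 subjects, k = 2)
icc(x, "icc_3_1")
#> ICC(3,1) two-way mixed, consistency: 1.0000  (n = 6 subjects, k = 2)
```

The constant 0.1 mm shift between observers leaves consistency perfect
but penalises absolute agreement — the reason inter-observer designs
report ICC(2,1).

A full paired study:

```r
cfg <- study_config(n_patients = 20, modality_b_offsets = list(lat = -0.12),
                    rng_seed = 101)
res <- run_study(cfg, "study_out")
res$agreement[, c("metric", "n", "bias", "loa_low", "loa_high", "pearson_r")]
```

writes `metrics.csv`, `agreement.csv`, `reliability.csv` and a manifest;
the −0.12 s latency calibration offset injected into the emulated
infrared device reappears as a ≈ +0.12 s bias (ultrasound − infrared) in
the agreement report.

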