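---
title: "Measuring contraction and calcium kinetics in chambered cardiac organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contraction and calcium kinetics in chambered cardiac organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CCOmetrics)
```

# The measurement problem

A chambered cardiac organoid (CCO) is a self-organized cardiomyocyte
aggregate whose wall contracts rhythmically around a central cavity. In
brightfield video the chamber core is a lighter shade than the wall, and
the wall darker than the background, so a per-frame segmentation into
*outer* (whole organoid) and *inner* (chamber) regions turns a video into
an area time series. From that series this package derives the phenotypes
used to detect hypertrophic remodelling: wall thickness and its
week-over-week change, beat rate and rhythm variability, and fractional
shortening; a parallel path measures calcium-transient kinetics from
GCaMP fluorescence. This vignette explains the models behind each stage,
the tunable parameters, and the choices made where the problem is
genuinely open.

# The synthetic organoid and what it stands for

Real CCO videos are large, irregular and have no ground truth. The
generator in this package therefore renders an idealized organoid — a
concentric annulus with a bright chamber (default gray 200), darker wall
(120) and dark background (40), a 1-px anti-aliased rim, integer
quantization like a camera, and optional Gaussian pixel noise. The
circular geometry is a deliberate simplification: every area has the
closed form $\pi R^2$, so the generator doubles as an analytic oracle for
segmentation and for everything downstream. A low-order harmonic boundary
perturbation ($R(\theta) = R(1 + a\cos m\theta)$, with its exact area
correction $1 + a^2/2$) is available for robustness experiments; it is
off by default and no claim of morphological realism is made.

Beating is modelled as a train of contraction events. Beat-to-beat
intervals are drawn from a normal distribution truncated below at
$0.2\,\times$ the mean — the floor prevents physically impossible
overlapping contractions, and the truncated normal is an explicit choice
where no empirical interval distribution is available. Within each cycle
the inner radius follows an asymmetric cosine pulse: contraction over a
`contractionRiseFraction` (default 0.3) of the cycle, recovery over the
rest. The outer radius co-varies with a coupling factor (default 0.5):
with coupling below 1 the wall *thickens* at systole, exactly as a
contracting myocardial wall does. The programmed fractional shortening
follows in closed form,
$FS = 100\,(1 - c)\,\Delta / T_{dia}$ with $\Delta$ the inner-radius
excursion and $c$ the coupling, and is recorded in the ground truth.

Two conventions are worth stating. The recording starts at the onset of
the first contraction (the first systole sits at
`riseFraction × first interval`), which makes a zero-variability 1 s
rhythm over 30 s contain exactly 30 beats. And a trailing beat enters the
ground truth only when at least roughly a third of its recovery is inside
the recording — a contraction whose recovery is never sampled is not
localizable by any detector, so keeping it in the truth would only
manufacture disagreement about an event the data do not contain.

Default study conditions: 256-px frames, 100/50 px diastolic radii, 0.8 s
mean interval (75 bpm) with 0.08 s SD, 20% inner-radius pulsation, 30 s
at 10 frames/s (300 frames), pixel noise SD 5 gray levels. These mirror a
mid-size organoid recorded on an ordinary inverted microscope; the frame
rate and duration match the 300-frames-per-video sampling the analysis
was designed around.

What the generator does **not** emulate: irregular and textured organoid
outlines, focus drift, stage motion, debris, uneven illumination,
photobleaching, or multiple organoids per field. Passing the recovery
tests therefore demonstrates correctness of the measurement definitions
and robustness to sensor-style noise — not robustness to every artifact
of live microscopy.

# Segmentation

Each frame is normalized to $[0,1]$, smoothed with a Gaussian
(`smoothingSigma`, default 2 px), and thresholded. The organoid/background
threshold starts from Otsu's criterion and is then refined to the midpoint
between the background mean and the mean of the *wall* class (the dominant
dark foreground mode, identified by a second Otsu split of the foreground;
when the dark sub-class is only a sliver of the foreground it is
edge-ramp pixels of a chamberless organoid, and the bright class is taken
as the wall instead). The refinement matters: a raw global threshold
drifts upward with the mass of the bright chamber and systematically
shaves the outer boundary; the midpoint cuts the background-to-wall edge
ramp at half height, which is unbiased. The outer mask is the largest
connected component (ties broken by lowest centroid row, then column)
with holes filled; frames with no component of at least `minObjectPx`
(default 64) are flagged as failures, never silently returned as zero.

The chamber is found by a second Otsu threshold restricted to interior
pixels. Because interior thresholding of a *chamberless* organoid just
splits noise, a candidate chamber must additionally (i) stay clear of the
smoothed boundary ramp by a margin of a few smoothing lengths, and (ii)
be separated from the wall by an intensity step of at least 10% of the
frame range. A solid organoid then correctly yields an empty inner mask
(a valid result), while a uniform blank frame yields a failure flag. A
configuration flag (`invertChamber`) handles recordings where the chamber
is darker than the wall.

Wall thickness is defined through equivalent circles,
$T = \sqrt{A_{out}/\pi} - \sqrt{A_{in}/\pi}$, rather than a local
distance transform: it is robust to outline irregularity, exact on the
synthetic geometry, and consistent with the area-based metrics. A
distance-transform variant (`thicknessMethod = "distmap"`) is provided
for sensitivity analysis only.

Across a recording, frames that fail segmentation are linearly
interpolated from their neighbours and flagged when they are fewer than
5% of the stack; beyond that the recording is rejected with a per-frame
report, on the view that a video that cannot be segmented should fail
loudly rather than produce quietly interpolated kinetics.

Pixel areas are reported in px² with no physical calibration; all derived
ratios (wall fraction, FS, fold changes) are calibration-free, and the
scale-equivariance of areas and thickness is covered by tests.

# Contraction kinetics

Contraction events are located on the outer-area trace: a centered moving
average (`smoothWindow`, default 3 frames), then the first-order
difference, with a systole called at every negative-to-positive zero
crossing — an area minimum, since contraction reduces the projected area.
Two filters reject spurious extrema: topographic prominence (walk from
the candidate to the nearest lower point on each side; the lower of the
two intervening cols must exceed `minProminenceFrac`, default 0.2, of the
trace range) and a minimum spacing (`minIntervalS`, default 0.2 s),
enforced deepest-first. Prominence is computed against the nearest
*higher* ground rather than between neighbouring candidates — the latter
collapses when noise creates dense candidate minima. Event times are
refined to sub-frame resolution by a three-point parabolic fit (the
waveform is locally quadratic at its extrema); refinement can be disabled
to keep events on the sampling grid. Interval statistics are invariant to
calling minima versus maxima on a periodic trace; the convention is
recorded in the output metadata. A constant trace returns an empty beat
series — zero beats is a result, not an error — and interval mean/SD for
fewer than two systoles are explicit `NA`, never zeros.

Each systole is paired with the preceding diastole (the area maximum
since the previous systole). Fractional shortening uses wall thickness at
those paired frames, $FS = 100\,(T_{sys} - T_{dia})/T_{dia}$, positive
when the wall thickens at systole — the thickness-change convention; the
echocardiographic chamber-diameter convention is available via
`convention = "chamber"`. Beats with non-positive diastolic thickness are
excluded and flagged. Whether contraction frequency should be reported
per second or per minute is ambiguous in practice, so both are emitted
(`frequency_hz`, `frequency_bpm`); FS is computed per beat and then
averaged, with the per-beat values retained so a global-extremum variant
can be reconstructed from the outputs.

Longitudinal normalization divides each organoid's weekly wall thickness
by its own week-0 value; organoids lacking a week-0 record are excluded
with a warning rather than silently assigned a fold of 1.

# Calcium-transient kinetics

The fluorescence model is the classic double-exponential pulse
$(1 - e^{-t/\tau_{up}})\,e^{-t/\tau_{down}}$, rescaled to a programmed
amplitude, on a baseline with optional linear drift and Gaussian noise.
Defaults — $\tau_{up} = 0.06$ s, $\tau_{down} = 0.18$ s, 1 s beat
interval, 100 Hz sampling, 30 s — describe a fast calcium reporter in a
spontaneously beating organoid and were chosen under two structural
constraints. First, the transient must essentially complete within one
beat ($\approx 4.6\,\tau_{down}$ plus the upstroke shorter than the
interval): when consecutive transients overlap, the trace never touches
the true baseline and *no* estimator can recover it from the data, which
silently biases every amplitude-relative duration. Second, the upstroke
must span several samples for a depolarization duration to be measurable
at all, which requires on the order of 100 Hz for a 60 ms time constant.
Slower reporters or faster rhythms will push measurements against these
limits, and the truncation flags below are how that manifests.

The baseline is a rolling low percentile (default the 10th over a 5 s
window; windows are clipped at the trace edges, and a window longer than
the trace falls back to the global percentile with a warning). Peaks are
local maxima of the baseline-subtracted trace under the same prominence
and spacing rules as the beat detector. Per transient: amplitude is the
smoothed subtracted value at the peak; the onset is the last pre-peak
crossing of `onsetFrac` (default 0.1) of the amplitude, located on the
*raw* subtracted trace — the upstroke is steep, so the crossing is
noise-robust there, while smoothing would bias it early; the end is the
first post-peak crossing down to `endFrac` (default 0.1), and
repolarization 30/60/90 are the first decays through 70/40/10% of the
amplitude, all linearly interpolated between samples. The peak *time* is
refined parabolically because, under noise, the raw argmax of the
flat-topped pulse is biased toward the slow (decay) side. CTD with 10%
onset/end fractions is a "CTD90"-style measure; the fractions are
configurable and stamped into the outputs. Searches are bounded by the
neighbouring peaks, so a decay truncated by the end of the recording or
masked by the next transient leaves the affected values as explicit `NA`.

Depolarization speed is computed as amplitude divided by upstroke
duration — the mean rate of fluorescence *rise*. The source description
of this quantity ("mean fluorescence decreased per second") is
self-contradictory for an upstroke measure; this package treats it as an
erratum and documents the direction here. Peak intensity is
baseline-subtracted, again a choice the outputs record rather than hide.
Per-recording summaries average each metric over valid events within a
measurement window (default the first 30 s).

# Cohort statistics

The comparison policy is: two-sided Mann-Whitney U when either group has
fewer than `smallNCutoff` observations (default 8 — "small" is not
defined more precisely anywhere authoritative, so the cutoff is explicit,
configurable and recorded in every output row), otherwise Welch's t test;
Student's pooled-variance t is available by explicit request, matching
the convention used for calcium-kinetics and qPCR-style comparisons. The
exact rank test is used whenever both groups are below 50 and tie-free,
the normal approximation with continuity correction otherwise, and the
test actually applied is always reported. Everything is two-sided and no
multiple-testing correction is applied, matching the comparison design
the tables emulate. Stars follow the p < 0.05/0.01/0.001/0.0001
convention, with strict inequalities at the boundaries.

The cohort simulator drives validation here: groups of organoids imaged
weekly with per-week multipliers on wall thickness (applied by moving the
inner radius), beat rate, interval SD and pulsation. Each organoid keeps
a jittered base geometry across weeks, like a re-imaged specimen, and
per-group seed offsets control whether groups are independent (the
default) or exactly noise-matched.

# Single-cell QC

Cells are retained when their detected-feature count lies in an
*inclusive* [2000, 7500] band ("between" is read inclusively; the
boundary rule is asserted by a regression test) and their mitochondrial
count fraction is *strictly* below 0.10; genes are retained when
expressed in at least 10 of the *retained* cells. The cell filter runs
first, and the order is load-bearing: a gene expressed in 12 cells of
which 5 fail QC sees only 7 qualifying cells and is dropped. Mitochondrial
genes are recognized by a case-insensitive `MT-` prefix (human
nomenclature). MatrixMarket triplets are read and written with
orientation auto-detection from the name counts. The synthetic
count-matrix generator programs exact per-cell feature counts and
near-exact mitochondrial fractions, so the filter is verified against a
brute-force per-cell/per-gene oracle rather than against itself.

# Numerical choices and degenerate inputs

- Timestamps are always frame index × interval; container metadata is
  ignored.
- TIFF output is stored on the 16-bit grid, so integer gray levels in
  [0, 65535] round-trip exactly; trace CSVs round-trip to 1e-6.
- Color frames are converted by the unweighted channel mean.
- A constant trace (to floating-point residue, 1e-9 relative) has zero
  beats; constant frames fail segmentation with a reason string.
- All crossing times are linearly interpolated between samples; extrema
  are refined by three-point parabolas with the offset clamped to half a
  frame.
- Undefined metrics are `NA` throughout, never 0.
- Cohort sub-seeds are expanded from one master seed by a fixed integer
  recurrence, so cohorts are reproducible organoid-by-organoid and all
  derived seeds stay within 32-bit range.
- Pipeline outputs embed the package version, an MD5 hash of the
  canonical YAML serialization of the configuration, and the seed;
  identical configuration and seed reproduce byte-identical files.

# Validation scale

The test suite and the acceptance script run entirely on synthetic data:
single annulus frames at 256 px; 160-px videos of 5–30 s for kinetics
(three 30 s recordings, about 110 beats, back the rate and rhythm
recovery); an 8 s two-group, two-week cohort of 16 videos for the
thickening fold; 1000 metric-level null simulations for the type-I error
of the comparison policy; and count matrices of 100 cells × 9000 genes.
These sizes were chosen so the full validation runs in a couple of
minutes on a single CPU while keeping every recovery estimate comfortably
inside its tolerance; they are package choices, not statements about the
scale of any particular experiment.

# Known limitations

- One organoid per field; no tracking, registration or drift correction.
- Segmentation assumes the chamber contrast direction is known (a flag,
  not an inference) and a wall at least a few smoothing lengths thick.
- Equivalent-circle thickness is a global summary; strongly lobed walls
  need the distance-transform variant and caution.
- The calcium path measures relative kinetics, not absolute calcium; no
  photobleaching correction beyond the rolling baseline, and overlapping
  transients truncate repolarization metrics by design.
- Rhythm analysis stops at interval SD; no arrhythmia classification.
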