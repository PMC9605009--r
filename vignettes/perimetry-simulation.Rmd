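---
title: "Simulating head-mounted static perimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating head-mounted static perimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisim)
```

perisim simulates a gaze-tracked, head-mounted static perimeter end to end:
the test grid and its bowl geometry, the photometric decibel scale, the
bisection thresholding strategy, frequency-of-seeing observers, complete
exams, grayscale rendering, and the agreement statistics used to compare two
perimetric devices. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open.

## The test pattern and its geometry

The 30-2 pattern is a square lattice with 6° spacing, offset 3° from both
meridians, restricted to the central 30° of visual field. The lattice
coordinates alone do not determine the pattern: a corner point such as
(27, 27) lies 38° out and is never tested. `build_grid_30_2()` keeps every
lattice point with eccentricity ≤ 28.5°, which reproduces exactly the
canonical 76-point pattern — rows of 4/6/8/10/10 points per hemifield, 38 per
hemifield, 19 per quadrant. The choice of 28.5° is not delicate: the nearest
excluded lattice point lies at 29.7°, so any radius in (28.46°, 29.70°)
yields the same pattern. Laterality fixes the nasal/temporal convention
(temporal = +x for a right eye), and the two points flanking the physiologic
blind spot sit at (temporal 15°, ±3°).

Stimuli live on a virtual bowl of radius 330 mm centred at the eye. Field
angles (x, y) map to the bowl along the direction `normalize(tan x, tan y, 1)`
scaled by the radius, so every stimulus subtends a constant visual angle
regardless of eccentricity. Gaze-contingent placement composes angles by
proper 3-D rotation, not addition: the target direction is rotated by the
rotation carrying the straight-ahead axis onto the measured gaze direction.
Additive angle composition is wrong off-axis by up to several tenths of a
degree at 20–30° eccentricities; the rotation construction preserves retinal
eccentricity to numerical precision (the test suite verifies < 1e-9° over
1000 random gaze/target pairs). A combined angle reaching 90° would leave the
forward hemisphere; the exam engine treats this as an off-display event and
retries with the next gaze sample.

The Goldmann size III stimulus is a 4 mm² circle defined at the historical
300 mm bowl, giving an angular diameter of `2·atan(sqrt(4/π)/300)` ≈ 0.431°,
conventionally printed 0.43°. At a 330 mm bowl 4 mm² would subtend only
≈ 0.39°, so the two published figures (4 mm², 0.43°) are mutually
inconsistent at this radius. We treat the *angular* size as normative —
perception depends on visual angle — and derive the physical extent on the
bowl from it (`stimulus_extent_on_bowl(0.431, 330)` ≈ 2.48 mm).

## Photometry

Perimetric decibels are attenuation relative to a 0-dB reference of
10,000 apostilbs (asb), the Humphrey convention: `L(dB) = 10000·10^(−dB/10)`
asb, with 1 asb = 1/π cd/m² exactly. This reproduces every printed anchor:
40 dB ↔ 1 asb ↔ 0.318 cd/m², and a display ceiling of 125.73 cd/m²
(395 asb) ↔ 14 dB, which is why 14 dB is the brightest testable stimulus on
such a display. Two related subtleties are worth recording. First, the exact
dB value of the 125.73 cd/m² ceiling is 14.034 dB, not 14; the staircase uses
the nominal integer 14 as its interval endpoint while `clamp_to_device()`
enforces the exact physical floor. Second, a background of 10 cd/m²
converts to 31.42 asb under exact π, while 31.5 asb circulates in the
literature (it corresponds to a rounded conversion constant); we use exact π
throughout.

## The bisection staircase

Each location is thresholded by interval bisection on [14, 40] dB. The next
stimulus is the midpoint of the current interval; a seen response raises the
lower bound to the presented intensity (seeing attenuation *a* implies
sensitivity ≥ *a*), a not-seen response lowers the upper bound; testing stops
when the interval is narrower than 1 dB and the midpoint is the threshold.
From the full range the width halves 26 → 13 → 6.5 → 3.25 → 1.625 → 0.8125,
so an unseeded staircase always terminates in exactly five presentations and
the estimate is within 0.40625 dB (half the terminal width) of a
deterministic observer's true threshold.

Three aspects are underdetermined by the verbal description and were fixed as
follows:

* **Bound orientation.** Seen ⇒ lower := presented. This is the only
  orientation consistent with dB as attenuation.
* **Seeding.** The fixation point (0, 0) — not one of the 76 — is tested
  first, unseeded, so its first stimulus is 27 dB. Its threshold seeds the
  remaining staircases as the *first presented intensity only*; the interval
  stays [14, 40] and the first update bisects from the seed. "Starting
  brightness" is a statement about the stimulus, not the interval. All 76
  points are seeded by the central threshold by default; seeding from the
  mean of completed neighbours within 8.5° is available as a clearly-labelled
  extension (`seeding = "neighbour"`), as is no seeding at all.
* **Floor/ceiling flags.** A staircase whose lower bound never left 14
  (observer effectively blind there) is flagged `floored`; one whose upper
  bound never left 40 is `ceilinged`. True sensitivities below the device
  floor are unmeasurable and report as ≈ 14.4 dB floored.

Staircases are completed one location at a time; interleaving presentations
across locations (as some commercial strategies do) is deliberately not
modelled.

## Simulated observers

Truth is a "hill of vision": apex sensitivity `s0` declining linearly with
eccentricity plus Gaussian point scatter, defaults 33 dB, 0.3 dB/°, 1 dB —
conventional normative values for a mid-adult healthy eye (not fitted to any
dataset; all exposed as arguments). Clinical defects are injected by
subtracting a depth over a shaped point set: blind-spot pair, nasal step,
arcuate bundle defect, quadrantanopia, and a peripheral "rim artifact"
mimicking an eyeglasses frame displaced over the field.

Responses follow a frequency-of-seeing model:
`p(seen) = fp + (1 − fp − fn)·Φ((t − presented)/σ)` with psychometric spread
σ (`fos_slope`, default 1 dB), false-positive floor `fp` and false-negative
ceiling `fn` (defaults 0.03). Because this simulated engine presents no
catch trials, fp and fn are modelled inside the psychometric equation rather
than as separate catch-trial streams.

Gaze wander is AR(1) per axis at the eye tracker's 120 Hz sampling rate with
stationary SD `gaze_sd` (default 1°, within the 0.5–1.1° accuracy bracket of
consumer eye trackers) and persistence 0.95 per sample (≈ 0.16 s drift time
constant). During an exam, with tracking **on** the stimulus is repositioned
with gaze and lands on the intended retinal location; with tracking **off**
the effective retinal location is displaced by the current gaze error, and
truth is evaluated there by inverse-distance weighting over the four nearest
grid points (exact on lattice nodes, smooth between them — plain
nearest-neighbour lookup would create step artifacts at cell borders).
Because presentations are ≥ 1.7 s apart, the AR(1) autocorrelation between
consecutive presentations is ≈ 3·10⁻⁵, so the exam engine draws stationary
gaze samples per presentation; `gaze_trace()` provides the full-rate process.

A consequence worth noting: on a *smooth normal* field, tracking confers only
a small advantage, because displacing the sampled location by ~2° changes a
0.3 dB/° hill by well under a decibel. The advantage becomes decisive on
fields with steep defect borders (arcuate scotomas, nasal steps), which is
precisely the clinical situation; the acceptance suite therefore tests the
tracking contrast on glaucomatous fields and parameter recovery on normal
fields.

## The paired-device cohort generator

For agreement statistics we simulate a cohort of eyes measured on two
devices. Per eye: truth (apex drawn with between-eye SD 4 dB, about the
spread of mean deviation in a mixed clinical cohort; per-point scatter 2 dB),
then each device observes truth + a *shared* per-point distortion (SD
`shared_sd`, common to both devices) + a per-eye *device bias* (SD
`eye_bias_sd_*`) + independent per-point noise (SD `indep_sd_*`). Reliability
indices FL/FP/FN are drawn uniformly in configurable ranges; MD/PSD/VFI are
derived summaries carried as passthrough metadata, never recomputed from
normative data.

The design of the noise budget matters. Independent *per-point* noise
averages away in a 74-point mean (its contribution to the global-mean
variance is σ²/74), so realistic point-level noise alone cannot pull the
correlation of paired global means much below 1. What separates devices in
practice is eye-level disagreement — calibration, wear, artifact — and that
is what the per-eye device bias term models. The expected global-mean
correlation has the closed form implemented in `nominal_global_r()`:
`r = B / sqrt((B + u_a)(B + u_b))` with `B` the between-eye variance common
to both devices and `u_x` each device's own eye-level variance;
`eye_bias_for_r()` inverts it. A bias SD of ≈ 2 dB per device yields a
nominal global r of 0.8 at these defaults. Monte-Carlo tests confirm the
calibration: over 50 seeds at 65 eyes the mean sample r is within 0.05 of
nominal at r ∈ {0.3, 0.5, 0.8}, and a single 65-eye draw at nominal 0.8
falls in [0.65, 0.90] (the Fisher-z sampling band).

## Grayscale rendering

Thresholds render on the perimetric grayscale: 14 dB exactly black (0),
40 dB exactly white (255), interior values linear on gray levels 1–254 via
round-half-up of `1 + 253·(dB − 14)/26` (the rounding rule is our choice;
linearity and the endpoints are the convention). Rasters span ±30.5° at a
default 4 px/°. The `tiles` style paints each location's 6°×6° cell —
an integer-only pipeline, bit-exact across platforms, written as plain-text
PGM (the reference format; PNG is a convenience). The `interpolated` style
smooths within the tested region only. Both are provided because published
grayscale maps are smoothed but the smoothing is never specified.

## Comparison statistics

Regional mean sensitivities are plain arithmetic means over the region's
points — global, hemifields, quadrants, and glaucoma-hemifield-test (GHT)
sectors — with the blind-spot pair excluded by default (configurable).
Because the published GHT sector figure is not recoverable from text, the
default sector map is the package's own approximation of the canonical
clusters: five mirrored sector pairs sweeping the nasal-step, paracentral
and arcuate zones (|x| ≤ 21°, |y| ≤ 21°), peripheral ring and blind-spot
points unassigned — and any assignment can be supplied as a CSV
(`read_sector_map()`).

Pearson correlations (via `stats::cor.test`, verified in tests against the
raw sum formula to 1e-12) are classified strong (r ≥ 0.7), moderate
(0.4 ≤ r < 0.7) or weak (r < 0.4), boundaries inclusive on the stronger
side. Zero-variance series yield an explicit undefined flag, never a coerced
0 or 1. The reliability filter excludes a record iff FL > 20% **or**
FP > 15% **or** FN > 30%, strict inequalities — a record exactly at a
threshold is kept. Paired comparisons use the standard paired t
(`stats::t.test`), with identical vectors or constant differences flagged
undefined. No multiple-comparison adjustment is applied across regions, and
none is claimed. `comparison_report()` assembles filter counts, regional and
point-wise correlations, and the global paired t into one JSON-serialisable
object with a 76-cell classification grid.

## Problem sizes, tolerances and degenerate inputs

The simulation suites run at the scale the analyses are defined at: 20
seeded exams for parameter recovery (RMSE < 1.5 dB against truth clamped to
[14, 40]), 20 paired exams for the tracking contrast, 65-eye cohorts × 50
seeds per nominal r for correlation recovery. A full simulated exam is 77
staircases (fixation + 76), typically 390–460 presentations, ≈ 11–13
simulated minutes at the default 1.7 s per presentation.

Numerical conventions: angle identities hold to 1e-9°; photometric
round-trips to 1e-12 relative; degenerate inputs fail loudly (angles ≥ 90°,
non-positive luminances, inverted staircase bounds, incomplete 76-point
files each raise descriptive errors naming the offending value or
coordinate). Exams are exactly reproducible from two integers: the
observer's response-stream seed and the testing-order seed.

## What the simulation does and does not show

The simulated observer is stationary: no fatigue, learning, blinks, pupil
change or headset slippage, and the gaze model is a homogeneous AR(1) rather
than saccades plus drift. The cohort generator makes no attempt to match any
particular clinical case mix. Passing tests therefore demonstrate that the
*engine* — geometry, photometry, staircase, rendering, statistics — behaves
as specified and that tracking helps under the stated wander model; they do
not certify clinical agreement between any two real devices. Summary indices
MD/PSD/VFI require normative databases and are carried as metadata only;
Bland–Altman limits of agreement are likewise out of scope.
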