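---
title: "Glottal area waveform parameterization and the spatial-resolution study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glottal area waveform parameterization and the spatial-resolution study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gawr)
```

## The problem

In laryngeal high-speed videoendoscopy (HSV) the vibrating vocal folds are
filmed at several thousand frames per second. The pixel area enclosed between
the folds, tracked over frames, is the glottal area waveform (GAW); a large
family of quantitative measures — jitter- and shimmer-like perturbation
quotients, open/closing quotients, left–right symmetry indices, declination
rates — is computed from it and used to characterize healthy and disordered
phonation. Many of these measures are expressed in pixels or pixels per
second, so the spatial resolution of the camera (and, equivalently, the
endoscope–glottis distance) is a potential confounder: the same phonation
recorded at half the linear resolution yields a quarter of the pixels.

`gawr` implements the full pipeline needed to study this sensitivity on
synthetic data with known ground truth:

1. **Synthesis** (`subject_config()`, `generate_gaw()`, `render_video()`,
   `generate_cohort()`): parametric GAWs and rendered image stacks of an
   oscillating, lens-shaped glottis.
2. **Resolution reduction** (`block_downsample()`, `make_triad()`): 2×2 and
   4×4 pixel averaging, producing the SR1/SR2/SR3 triad of one recording at
   full, half and quarter linear resolution.
3. **Segmentation** (`make_seed_grid()`, `region_grow()`,
   `segment_sequence()`): seeded region growing below a brightness
   threshold, midline computation, and extraction of the total and
   left/right partial GAWs.
4. **Parameterization** (`detect_cycles()`, `select_cycles()`,
   `cycle_primitives()`, `compute_all()`): maximum-based cycle detection and
   the 50-measure catalogue.
5. **Statistics** (`run_triads()`, `omnibus_test()`, `posthoc_tests()`,
   `study_statistics()`, `summarize_study()`): repeated-measures comparison
   of every measure across the three resolutions.

## The synthetic subject model

Each simulated subject is one sustained phonation. Cycle `i` has period
$T_i = (f_s/F_0)\,g_i$ frames and peak area $A_i = A_{\max} h_i$ px, where
$g_i$ and $h_i$ are Gaussian factors with mean 1 and standard deviations
`period_jitter` and `amp_jitter`, truncated at three standard deviations
(inverse-CDF sampling, so truncation is exact). Within a cycle the area
follows a raised sine-squared pulse over the open fraction `open_quotient`
of the period and is exactly zero otherwise — a "true closed phase" in the
sense that the segmented area reaches 0 px. The left and right folds carry
shares $1/(1+r)$ and $r/(1+r)$ of the total ($r$ = `asym_amplitude`), and
the right pulse may lag by `asym_phase` of the period. With a nonzero lag
the jointly closed window shortens by the lag, which is why configurations
must satisfy `open_quotient + asym_phase < 1`.

Rendering draws the glottis as two mirrored circular-arc (lens) halves about
a straight anterior–posterior axis. The axis runs through the centers of one
pixel row, so the drawn region splits exactly into rows above (left fold),
rows below (right fold) and the axis row, which counts half to each side;
the per-frame sagitta of each half is chosen so its circular-segment area
equals the analytic partial waveform (inverse interpolation of the monotone
area–sagitta relation). Additive Gaussian pixel noise (`noise_sd`, default 8
intensity steps) is applied last and intensities are clipped to `[0, 255]`.
The exact rendered pixel counts per frame are returned as ground truth.

Defaults mirror a clinical recording setup: 4000 frames/s, 1000 frames
(250 ms), 512×256 px sensor frames, tissue at intensity 180 and glottis at
60. Cohort presets sample the fundamental frequency uniformly from
180–250 Hz (females) and 110–150 Hz (males), and the maximal glottal area
from 1150–1750 px and 900–2700 px respectively — chosen so that, after ±3
s.d. amplitude perturbation and rendering discretization, realized maxima
stay inside the ranges observed clinically (978–2057 px for females,
742–3214 px for males). The perturbation defaults
(`period_jitter = 0.01`, `amp_jitter = 0.03`) are plausible magnitudes for
healthy sustained phonation; no published distributional model exists for
them, so they are stated choices rather than fitted values.

What the generator does **not** emulate: mucosal-wave texture, specular
highlights, endoscope motion and rotation, illumination gradients, and
non-elliptic glottis shapes (hourglass closure patterns, posterior gaps).
Passing tests therefore demonstrate correctness of the measurement chain
and the direction of resolution effects, not clinical performance on real
recordings.

## Resolution reduction

`block_downsample()` replaces each `f × f` block (f = 2 or 4) by its
arithmetic mean rounded to the nearest integer. Halves are rounded away
from zero; this choice is fixed and documented because the rounding rule
for exact halves is otherwise ambiguous. Both reductions are computed
directly from the original, so rounding is applied exactly once — iterated
2×2 averaging can differ from direct 4×4 averaging in the rounding step,
and the tests exhibit such a block. Frame dimensions must be divisible by 4
before a triad is built; the cropping helpers keep regions of interest on
multiples of 4 so one ROI maps exactly onto all three resolutions.

## Segmentation

Region growing starts from every point of a regular seed lattice and adds
any pixel that is **strictly darker** than the brightness threshold and
4-connected (8-connectivity optional) to an already added pixel. A grid of
seeds, rather than hand-placed points, keeps the segmentation objective and
ensures no dark pocket inside the glottis is missed. The grid is drawn on
the lowest resolution and condensed by the resolution factor for the higher
ones, so the mesh density relative to the glottis is constant across a
triad. Thresholds are operator-set (for synthetic subjects: derived from
the known intensity levels), never estimated from the data — automating the
choice would silently change the method.

For synthetic triads the default threshold sits **half an intensity step
above** the glottis/background midpoint. With the strict darker-than rule
and integer block means, a threshold exactly at the midpoint would exclude
every block of a reduced resolution that is exactly half covered by the
glottis (at SR2, a block then needs 3/4 coverage), deflating SR2/SR3 areas
systematically; the half-step offset makes half-covered blocks count and
leaves only genuine discretization error. For glottides only a few SR3
pixels wide the boundary blocks dominate and the areas of the reduced
resolutions overshoot the nominal 1/4 and 1/16 — that residual is a real
resolution effect, not a bug, and it is the regime in which the measured
parameters react most strongly.

The midline is the chord between the two contour points at maximal mutual
distance, computed once on the frame of maximal area and held fixed; its
length is the glottal length. Pixels are assigned to the left or right side
by the sign of the cross product against the posterior→anterior direction
(anterior = lexicographically smaller endpoint), with pixels exactly on the
line counting half to each side — so left + right equals the total area
exactly. The construction is deterministic; its robustness degrades with
shrinking pixel counts, which is visible in the symmetry measures at SR3.

## Cycles and the parameter catalogue

Cycles are detected at "sufficiently distinct" local maxima. Distinctness
is operationalized as topographic prominence of at least `prominence_frac`
(default 0.25) of the global dynamic range; equal-height summits do not
cancel each other's prominence, plateaus resolve to their first frame, and
retained peaks must be at least `max(4, 0.5 × median gap)` frames apart
(kept greedily by height). Starting with the third detected cycle, 20
consecutive cycles are selected; per-cycle primitives (period, extrema,
dynamic range, energy, open/closing/opening/plateau times) feed the
catalogue. The closing time runs from the cycle-start maximum to the first
zero and the opening time from the last zero to the final frame of the
cycle (to the area minimum when no full closure occurs); the plateau is the
band at or above 0.95 of the cycle maximum.

The catalogue holds 50 measures in seven groups — fundamental period (FPM),
period/amplitude/energy perturbation (PPM/APM/EPM), symmetry (SM), glottal
dynamic characteristics (GDC) and mechanical measures (MM). Fifteen
measures are mathematically dependent on others (e.g. MCD = 1000/F0,
Jit(%) and friends are rescalings of MJit, RAPK = RAPB·(N−1)/(N−2), APF ≈
11.51·MShim for small perturbations, SQ/SI/RQ/AQ are recombinations of the
phase durations) and carry an exclusion flag: they are computed and
reported but omitted from the main statistics, leaving 35 relevant measures
with group sizes 1/6/7/4/7/5/5. Where the original references define a
measure only loosely, the formula is pinned here so that the documented
qualitative behavior holds: PVI and AVI are order-invariant variance
measures; AVI, PhAI, PhA, SpSI, SpS and GGI can reach zero or negative
values; GGI uses selection-global extrema while GAI averages per-cycle
ratios; MADR averages per-cycle maximal declination while PCV takes the
global maximum; MADR and PCV are reported in Mpx/s.

## Statistics

For each measure and sex, values form an `n × 3` matrix over SR1/SR2/SR3.
The omnibus comparison uses a one-way repeated-measures analysis of
variance when every condition passes a Shapiro–Wilk normality check at
α = 0.05, and the Friedman rank test otherwise; the branch can also be
forced. In the parametric branch, sphericity is assessed with Mauchly's
test and the Greenhouse–Geisser correction applied when it rejects at 0.05
(the F statistic and ε are computed from the textbook decomposition; the
uncorrected p is cross-checked against `aov()` error strata in the tests).
Post-hoc pairwise tests (paired t or Wilcoxon signed-rank) are
Bonferroni-corrected by the factor 3 — one per resolution pair — and a
measure counts as significant at corrected p ≤ 0.05. Data constant across
conditions for every subject yield p = 1 by convention. Subjects whose
segmentation or cycle analysis fails are dropped listwise with a message.

## Numerical choices and degenerate inputs

* Rounding of block means: halves away from zero, applied once per
  reduction.
* Truncated Gaussian perturbation factors via inverse-CDF sampling; all
  randomness flows through R's RNG, so a configuration seed reproduces a
  subject bit-identically (rendering consumes `rng_seed + 1` for pixel
  noise).
* Cycle-detection ties (plateau maxima) resolve to the first frame;
  cross-correlation lag ties in PhA resolve to the smallest absolute lag,
  negative first.
* Empty masks are valid segmentation results (area 0); an empty reference
  frame (no glottis anywhere) aborts midline computation with an error.
* Zero dynamic range, zero cycle energy, a flat partial waveform, or a
  waveform that never opens abort the corresponding parameter group with a
  named error rather than returning NaN.
* At zero amplitude perturbation AVI is −∞ dB (log of a zero variance);
  this is the measure's true optimum and survives only in noise-free
  synthetic input.

## Problem sizes

The test-suite study runs 20 subjects per sex at 1000 frames and 256×128-px
frames with the cohort presets above; the acceptance script runs 12 per
sex. A 256×128 frame holds the full preset glottis range with margin — a
larger sensor frame adds only background that the ROI selection discards —
and keeps one subject (rendering, triad, three segmentations,
parameterization) at a few seconds of CPU. The per-sex sample size matches
the reference cohort design; single-triad checks use one mid-range female
configuration.

## Known limitations

* The synthetic glottis is convex and smooth; segmentation of real
  recordings faces texture, shading and partial occlusion that the noise
  model does not represent.
* The midline chord construction is one documented choice among several
  plausible ones; real systems may smooth the contour first.
* OQ measured on rendered video is lower than the configured open quotient
  because sub-half-pixel openings quantize away — by design, this is the
  mechanism that lengthens the closed phase at reduced resolution.
* The repeated-measures model covers the single within-subject factor
  (resolution); no between-subject factors are modeled.
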