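# gawr — glottal area waveform analysis and spatial-resolution sensitivity

In laryngeal high-speed videoendoscopy (HSV), the pixel area enclosed
between the vibrating vocal folds — tracked frame by frame — is the glottal
area waveform (GAW). Clinicians and voice scientists compute dozens of
measures from it: jitter- and shimmer-like perturbation quotients, open and
closing quotients, left–right symmetry indices, and slope measures such as
the maximum area declination rate (MADR). Many of these are expressed in
pixels, so the spatial resolution of the camera (or the endoscope–glottis
distance) is a potential confounder that can break comparability between
examinations and studies.

`gawr` is a research pipeline for quantifying that sensitivity. It

* synthesizes HSV-like image stacks of an oscillating, lens-shaped glottis
  with controllable per-cycle period/amplitude perturbation, closed-phase
  fraction, left–right asymmetry and pixel noise — with exact ground truth;
* reduces spatial resolution by 2×2 and 4×4 pixel averaging (rounded once
  to integer intensities), forming the SR1/SR2/SR3 *triad* of one recording;
* segments the glottis by seeded region growing on a regular grid of seed
  points (strictly-darker-than-threshold, 4-connected), splits it along the
  anterior–posterior midline, and extracts total and partial GAWs;
* detects maximum-based oscillation cycles, selects 20 consecutive cycles
  starting at the third, and computes a 50-measure catalogue in seven
  groups (FPM, PPM, APM, EPM, SM, GDC, MM; 15 mathematically dependent
  measures are flagged and excluded from the main statistics, leaving 35
  relevant ones);
* compares every measure across the three resolutions with a
  repeated-measures design: Shapiro–Wilk-gated choice between
  repeated-measures ANOVA (Greenhouse–Geisser-corrected when Mauchly's test
  rejects sphericity) and the Friedman test, with Bonferroni-corrected
  post-hoc pairs.

For the model details, numerical conventions and design choices, see the
methods vignette (`vignettes/gaw-resolution-methods.Rmd`).

## Worked example

```r
library(gawr)

cfg <- subject_config("female", f0 = 210, period_jitter = 0.01,
                      amp_jitter = 0.03, rng_seed = 7)
g  <- generate_gaw(cfg)      # analytic GAW triple + ground truth
ps <- compute_all(g$gaw)     # the 50-measure parameter set

ps[ps$name %in% c("F0", "MShim", "AmSI", "OQ", "MADR"), ]
#>   name group    value units excluded
#>     F0   FPM 209.9738    Hz    FALSE
#>  MShim   APM   0.1431    dB    FALSE
#>   AmSI    SM   1.0000 ratio    FALSE
#>     OQ   GDC   0.5827 ratio    FALSE
#>   MADR    MM   1.5600 Mpx/s    FALSE
```

The configured fundamental frequency (210 Hz) is recovered from the
detected cycle lengths; the 1% period and 3% amplitude jitter appear as a
small shimmer (0.14 dB); the folds are perfectly symmetric (AmSI = 1); the
open quotient is slightly below the configured 0.6 because sub-pixel
openings quantize away; and the glottis closes at about 1.56 Mpx/s.

A full triad experiment on a rendered cohort:

```r
cohort <- generate_cohort(5, rng_seed = 1, render = FALSE,
                          frame_height = 128, frame_width = 256)
triads <- run_triads(cohort)            # render, reduce, segment, measure
report <- study_statistics(triads)      # omnibus + post-hoc per measure
summarize_study(report)                 # per-group significance grid
relative_deviation(triads, "MADR")      # per-subject SR2/SR1, SR3/SR1
```

Pixel-bound mechanical measures scale with the pixel count (MADR falls
roughly 4-fold at SR2 and 16-fold at SR3), while F0 is essentially
resolution-independent.

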