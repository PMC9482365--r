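---
title: "Quantifying planarian electrotaxis: models, metrics and design choices"
author: "electrotax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planarian electrotaxis: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrotax)
```

## The assay

Planaria show cathodic electrotaxis: in a static electric field they
reorient and glide toward the negative electrode. The assay this package
quantifies places one worm in a narrow 60 mm trough (trapezoidal cross
section, 17.3 mm wide at the top, 4.4 mm at the bottom, 10 mm deep)
filled with water, applies a voltage across the long axis, and films the
trough from above at 8 frames/s against a bright backlit panel, so the
worm appears as a dark blob. Halfway through the trial the polarity is
reversed, forcing a worm that has reached the cathode to turn around and
cross the whole trough again — a much stronger behavioural test than a
one-way approach.

The long axis is split into four equal quadrants. The outer two contain
the electrodes; at any moment one of them contains the cathode. Two
per-worm metrics are computed separately before ("1") and after ("2")
the swap:

* **f_cat-1/2** — the fraction of phase time spent in the quadrant
  containing the current cathode;
* **f_mov-1/2** — the fraction of visible frames in which the worm's
  axial centre-of-mass coordinate moved *strictly* closer to the current
  cathode than in the previous frame.

Both are proportions in [0, 1]. A randomly moving worm is expected at
f_mov ≈ 0.5 and f_cat ≈ 0.25; a strongly electrotaxing worm exceeds both
by a wide margin. A 2 V differential across the 60 mm trough corresponds
to a mean axial field of `r round(field_strength(2, arena_geometry()), 2)`
V/cm.

### Metric conventions

Several small conventions matter for reproducibility and are fixed here:

* Quadrant bins are half-open, `[0, 15) … [45, 60]`, with the last bin
  closed; the boundary choice is measure-zero but deterministic.
* Scoring internally shifts coordinates so the current cathode sits at 0;
  the phase-2 metrics are judged against the *new* cathode.
* Ties (no strict approach) never count toward f_mov. The denominator is
  the number of visible frames in the phase, so even a worm that
  approaches on every step scores (n − 1)/n, because the release frame
  has no predecessor. No velocity threshold or persistence requirement is
  applied.
* The worm is invisible while occluded by an electrode (it has, after
  all, arrived). Occupancy attributes invisible frames to the last known
  quadrant — the only reading under which "time spent at the cathode" and
  "invisible at the cathode" are consistent. Frames before the first
  detection are excluded from occupancy denominators; this exclusion is
  recorded in the run manifest.
* The frame at the swap time belongs to phase 2 (half-open phase
  intervals).

## The synthetic-data generator

No public recordings of this assay exist, so the package is testable end
to end through a generative model whose defaults encode the assay's
stated conditions: a 60 mm arena imaged at 8 frames/s, worms of 2–12.4 mm
gliding at 1.02 mm/s (small), 1.36 mm/s (medium, interpolated) or
1.70 mm/s (large), a drift toward the current cathode, a polarity swap at
half time, and worm invisibility within 3 mm of an electrode (the
electrode thickness).

The motion model is a discrete-time persistent random walk with an
electrotaxis term:

* Each frame the worm either steps straight toward the current cathode
  (probability `electrotaxis_bias`) or takes a walk step whose direction
  is the normalised blend of the previous walk heading (weight
  `persistence`) and a uniformly random direction. The per-step heading
  is therefore the mixture `(1 − bias) · walk + bias · toward-cathode`.
  Applying the bias as a per-step mixture keeps the dose–response graded
  — the expected toward-cathode step fraction is `(1 + bias)/2` — rather
  than letting the drift compound through the heading memory, which
  would make any bias above ~0.5 behaviourally indistinguishable from
  pure drift.
* Step length is `speed/fps`; all four walls reflect both the position
  and the heading.
* `wall_affinity` adds a transverse pull toward the nearer long wall on
  walk steps, reproducing wall-hugging (and hence corner dwelling in the
  electrode quadrants) without touching the axial dynamics.
* The worm is released at the trough midpoint, like the real assay.

`persistence = 0.9` is the calibrated default. Under the normalised
blend the heading angle diffuses by roughly `(1 − p)` radians per frame,
so 0.9 yields gliding runs lasting tens of seconds — long enough that an
unbiased worm explores the whole trough within a 120 s trial, which is
what 0 V animals do (even small worms can cross the 60 mm trough inside
a trial). With substantially lower persistence the walk is too diffusive
to leave the central quadrants in 120 s and the 0 V null (≈25% occupancy
per quadrant) is not reproduced. A consequence worth knowing: a single
worm's phase score depends strongly on its release heading, so per-worm
f_mov distributions are wide and statistical properties should be
checked on cohorts, not individuals.

Cohorts are expanded deterministically: the master seed draws one child
seed per worm, so any subset of a design is reproducible independently
of the rest.

### Rendering

`render_frames()` draws each visible frame as a filled dark ellipse
(major axis = body length, 5:1 aspect, oriented along the current
heading) on a bright background (200 vs 40 intensity units) with
additive Gaussian pixel noise, plus a worm-free background frame, as the
real acquisition records. Frames include a half-body-length margin
around the trough — the slack left when rectangles are drawn around each
arena — so the silhouette is never clipped when the worm hugs a wall;
the accompanying `origin_mm` offset maps pixel coordinates back to arena
coordinates. The rigid ellipse does not model body flexion against the
walls, scrunching gaits, or partial occlusion at the electrode edge:
occlusion is all-or-nothing by centre-of-mass position.

## Tracking

Tracking mirrors the manual workflow it automates: split the composite
frame into per-arena stacks (`split_arenas()`), subtract the background
(absolute difference, so the dark worm becomes a bright blob), threshold,
keep the largest 8-connected component, and take the unweighted centroid
of its pixels — a thresholded particle-style centroid, not an
intensity-weighted one. Frames whose largest blob is smaller than
`min_area_px` are marked invisible and carry missing positions; no
interpolation or identity logic is applied.

Two defaults replace manual judgement:

* **Threshold.** Otsu's method on the pixelwise *maximum* difference
  projection. The maximum projection contains the worm's whole trail, so
  its histogram is strongly bimodal and the Otsu split is stable. (A
  median projection — the more obvious choice — fails: the worm rarely
  occupies one pixel in more than half the frames, so the median is pure
  noise and the threshold collapses to the noise floor.) A fixed scalar
  can always be supplied instead.
* **Minimum blob area.** 25% of the median detected-blob area across
  frames, which rejects noise specks without dropping partially occluded
  worms, and without requiring the tracker to know the worm's size in
  advance.

### Fidelity and its limits

On rendered stacks the tracker recovers centroids to well under one
pixel and visibility flags to ≥98%. The full
simulate → render → track → score round trip reproduces each f metric to
within 0.02 when imaged at 0.1 mm/px. At coarser scales (0.25 mm/px) the
binary-mask centroid quantises, and because f_mov uses a *strict*
inequality with no velocity threshold, slow axial drift can lose whole
runs of frames to quantisation plateaus (errors up to ~0.04 on f_mov,
independent of pixel noise). This is a genuine property of the metric,
not of the implementation: thresholded-centroid f_mov should be treated
with care whenever per-frame displacement approaches the pixel size.

## Morphometrics

Electrotaxis ability co-varies with relative head size, so the package
measures head:body ratios from binary masks. Body area is the pixel
count; body length is the maximum Feret diameter over the boundary-pixel
corners (each pixel treated as a unit square, as particle-analysis tools
do; a single-pixel mask has length 0 by convention). The head boundary
is an input annotation — in the original workflow heads were measured by
hand by a naive observer, and no automatic head detector is offered.
`head_ratio()` projects mask pixels onto the principal axis of the
mask's second moments, takes everything anterior to the annotated cut as
head, and reports length and area ratios. Both length terms in
`ratio_len` are axial extents along the principal axis, so the
cut-at-25% fixture recovers 0.25 exactly; for slender 5:1 worms the
axial extent and the Feret length agree to within 2%.

`ratio_response_model()` fits `f_mov_2 ~ ratio * voltage` and reports
the per-voltage slopes and the interaction term (parametric Type-II F,
plus an optional Freedman–Lane permutation p), which is the analysis
that links relative head size to post-swap electrotaxis.

## Statistics

The response variables are proportions, which often violate normality
and homoscedasticity, so the battery pairs parametric models with
assumption checks and randomization confirmations:

* `one_way_anova()` (voltage sweeps) and `factorial_anova()` (voltage ×
  size and similar designs). Factorial models use **Type-II sums of
  squares**, which coincide with the sequential decomposition for
  balanced data and remain order-invariant when cells are unbalanced.
  Electrotaxis is indicated not by a main effect but by the
  voltage-by-covariate interaction.
* `dunnett()` compares every voltage against the 0 V control with
  family-wise adjustment from the multivariate-t distribution (seeded
  Monte-Carlo integration, reproducible to ~0.001 in p).
* `tukey()` provides studentized-range-adjusted cell contrasts,
  optionally restricted to planned pairs (0 V vs 2 V within each level)
  while keeping the full family for the adjustment.
* `repeated_measures()` handles successive-treatment designs with
  subject as a blocking factor; the within-by-between interaction tests
  whether groups differ in their response to the treatment sequence.
* `paired_t_bonferroni()` implements the planned paired contrasts with
  a Bonferroni-adjusted alpha (0.05/6 = 0.008 for the six-comparison
  family).
* `assumption_checks()` runs Shapiro–Wilk on residuals and the
  studentized Breusch–Pagan Lagrange-multiplier test (n·R² of the
  squared-residual regression).
* `randomization_anova()` permutes the response freely for one-way
  designs and uses the Freedman–Lane residual-permutation scheme for
  terms of multi-factor models (residuals of the reduced model are
  permuted, preserving the other effects — the exchangeable quantity
  under the null). p-values use the add-one estimator
  `(1 + #{F* ≥ F})/(1 + n_perm)` and an exact enumeration mode is
  available for small two-group designs.

Post hoc procedures are intended to follow a significant omnibus test;
when the caller passes a non-significant omnibus p the result is
computed but flagged `gated`. Degenerate zero-variance inputs return
p = 1 with a flag rather than failing, so synthetic edge cases pass
through pipelines.

## Reproducibility plumbing

One flat YAML config drives all stages (arena geometry, run parameters,
master seed, cohort design); unknown keys are an error. `run_simulate()`
and `run_pipeline()` write CSV/JSON artifacts plus a manifest recording
the config hash, every seed, and the decision flags (threshold mode,
sums-of-squares type, occupancy attribution rule). Identical config and
seed give byte-identical outputs.

## Problem sizes used in the checks

The shipped test suite exercises the scenarios at desk scale, chosen as
the smallest cohorts at which the statistical contracts are sharp: 200
unbiased worms × 120 s for the null occupancy (each quadrant 25 ± 3%),
50 worms at bias 0.8 for the electrotaxis scenario (>50% cathode-quadrant
time), 30 rendered worms for speed recovery (1.70 ± 0.09 mm/s), 20
rendered worms for the round-trip fidelity bound, 100 random
trajectories against brute-force metric oracles, and 500-replicate null
simulations for the type-I error of the ANOVA, Tukey and Dunnett
procedures (0.05 ± 0.02).

## Known limitations

* The generator is a point-mass kinematic model: no scrunching or
  oscillatory head turning (seen at 3–4 V), no posture, no multi-worm
  arenas, and occlusion is purely by electrode proximity.
* Wall preference strength is a free parameter; the assay literature
  gives no quantitative value to fit.
* The renderer's rigid ellipse can overhang the trough walls into the
  image margin; real worms flex instead.
* f_mov is quantisation-sensitive at coarse imaging scales (see above).
* The electric field is summarised by its mean axial gradient; the
  spatial field inside the trapezoidal cross-section and current-density
  prediction are out of scope.
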