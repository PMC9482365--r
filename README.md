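# electrotax

Quantification of planarian electrotaxis from trough-arena image stacks.

Planaria exhibit cathodic electrotaxis: in a static electric field of
roughly 0.33 V/cm (2 V across a 60 mm trough) they reorient and glide
toward the negative electrode, and keep doing so after the field
polarity is reversed mid-trial. This package is for researchers running
(or re-analysing) that assay: it turns backlit video of one worm per
trough into per-worm electrotaxis scores and runs the associated
statistics, and it ships a synthetic-data generator so the whole
pipeline is testable without any recordings.

The core quantities, computed separately before ("1") and after ("2")
the polarity swap, are

* *f*<sub>cat-1/2</sub> — the fraction of phase time spent in the
  quadrant containing the current cathode (the trough's long axis is
  split into four equal quadrants; expectation 0.25 under random
  motion), and
* *f*<sub>mov-1/2</sub> — the fraction of visible frames *j* in which
  the axial centre-of-mass coordinate *y*(*j*) is strictly closer to
  the current cathode than *y*(*j* − 1) (expectation 0.5 under random
  motion),

plus phase-wise quadrant occupancies, mean gliding speed, and head:body
morphometric ratios. Group comparisons use one-way and factorial ANOVA
(Type-II sums of squares), Dunnett and Tukey post hoc tests,
repeated-measures models, Bonferroni-adjusted paired t-tests,
Shapiro–Wilk and Breusch–Pagan assumption checks, and Freedman–Lane
randomization tests.

## Worked example

Simulate a small two-group experiment (ten 0 V controls, ten worms with
a strong cathodic bias at "2 V", 120 s at 8 frames/s with the polarity
swap at 60 s), score it, and test for electrotaxis:

```r
library(electrotax)

arena <- arena_geometry()                       # 60 mm trough, 4 quadrants
cfg2  <- experiment_config(voltage_V = 2, duration_s = 120)
cfg0  <- experiment_config(voltage_V = 0, duration_s = 120)
design <- list(
  list(n = 10, label = "0V", config = cfg0,
       params = worm_params("large", electrotaxis_bias = 0)),
  list(n = 10, label = "2V", config = cfg2,
       params = worm_params("large", electrotaxis_bias = 0.8)))
cohort <- generate_cohort(design, arena, seed = 1)
scores <- score_cohort(cohort)

aggregate(cbind(f_cat_1, f_cat_2, f_mov_1, f_mov_2, mean_speed_mm_s)
          ~ label, scores, function(x) round(mean(x), 3))
#>   label f_cat_1 f_cat_2 f_mov_1 f_mov_2 mean_speed_mm_s
#> 1    0V   0.200   0.305   0.531   0.585           1.696
#> 2    2V   0.811   0.453   0.897   0.896           1.699

an <- one_way_anova(scores$f_mov_1, scores$label)
an
#>       term        ss df        F            p
#> 1   groups 0.6726937  1 42.89371 3.732038e-06
#> 2 residual 0.2822905 18       NA           NA

dunnett(scores$f_mov_1, scores$label, control = "0V",
        omnibus_p = an$table$p[1], seed = 1)
#> post hoc method: dunnett
#>   comparison  estimate        p_raw        p_adj
#> 1    2V - 0V 0.3667952 3.732038e-06 3.732038e-06
```

The control group sits at chance (*f*<sub>mov</sub> ≈ 0.5, first-phase
cathode-quadrant time ≈ 0.2–0.3), while the biased group moves toward
the cathode in ~90% of visible frames and spends 81% of the first phase
in the cathode quadrant; the drop in *f*<sub>cat-2</sub> reflects the
long trip back across the trough after the swap. The voltage effect is
significant (F(1,18) = 42.9, p < 10⁻⁵) and the Dunnett comparison
against the 0 V control confirms it.

The same metrics can be computed from images instead: render the cohort
(`render_frames()`, or `run_simulate(..., render = TRUE)` for TIFF
stacks), then `split_arenas()` → `track_com()` →
`score_trajectory()`. On rendered stacks the tracker recovers centroids
to sub-pixel accuracy and the scores agree with the ground-truth
trajectories to within 0.02 per metric at 0.1 mm/px.

## Documentation

The methods vignette
(`vignettes/electrotaxis-quantification.Rmd`) describes the generative
model and its calibration, the metric conventions (tie handling,
occlusion attribution, phase boundaries), the tracking defaults, the
statistical battery, and known limitations.
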