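# girdlekin

Six-degree-of-freedom pectoral girdle kinematics from marker-free biplane
x-ray motion analysis.

## What this package is for

In quadrupedal *suspensory* locomotion — the upside-down walking of
two-toed sloths (*Choloepus didactylus*) — forelimb reach is produced by
the whole pectoral girdle, not just the shoulder joint: the scapula glides
around the rib cage, the clavicle tethers the shoulder to the sternum, and
the thorax itself shifts and yaws. Biplane x-ray motion analysis recovers
the six degrees of freedom (three translations, three rotations) of each
skeletal element by posing bone models against two calibrated x-ray views.

`girdlekin` provides the quantitative machinery around such recordings,
for biomechanists working with digitized pose tables:

* **Rigid-body kinematics** — Euler-angle conventions (intrinsic xyz,
  `R = Rz·Ry·Rx`, degrees/cm), rigid-transform composition and inversion,
  and forward kinematics over the hierarchical "digital marionette"
  `global → 1st thoracic vertebra → {scapula → humerus, clavicle}`, with
  landmark trajectories relative to any reference segment.
* **Biplane DLT calibration** — the 11-parameter direct linear
  transformation
  `u = (L1·X + L2·Y + L3·Z + L4) / (L9·X + L10·Y + L11·Z + 1)` (and
  likewise `v`), solved by normalized linear least squares from a bead
  lattice; two-view triangulation with reported reprojection residuals;
  grid-based image distortion correction.
* **The gait pipeline** — stride segmentation with translations re-zeroed
  at touch down, speed ([0.2, 0.3] m/s) and symmetry ([0.4, 0.6])
  inclusion filters, 50+50-point time normalization over contact and
  swing, pooling into mean ± s.d. curves, endpoint summaries (contact
  amplitude = |lift-off − touch-down| of means; maximal amplitude over the
  full cycle), equal-variance t-tests between individuals, and
  digitization-repeatability summaries.
* **Virtual experiments** — "muting" selected DOFs at their touch-down
  value and re-deriving the elbow trajectory relative to the 1st thoracic
  vertebra, quantifying the displacing effect of scapular and humeral
  motions as per-axis amplitudes and % of total forelimb length (tfl).
* **Morphometrics** — summary statistics of comparative girdle
  measurements, relative scapula length, and tfl.
* **A seeded synthetic-data generator** — template-based stride
  kinematics with exact endpoint control, gait-parameter variability,
  digitization noise at repeatability magnitudes, and synthetic
  calibration scenes, so every stage is testable without recordings.

## Worked example

Morphometrics of the seven reference specimens, then a synthetic trial
through the full pipeline:

```r
library(girdlekin)

s <- summarize_measurements(girdle_measurements())
s[, c("measure", "mean", "sd", "n")]
#>          measure  mean   sd n
#> 1        scapula  7.98 0.67 7
#> 3        humerus 14.02 1.51 7
#> 5           ulna 16.68 2.25 7
#> 6           hand  9.36 0.52 5    # two missing entries excluded
relative_scapula_length(s)
#> [1] 21          # % of scapula+humerus+ulna: far below the ~30% of
#>                 # pronograde mammals
tfl <- total_forelimb_length(
  girdle_measurements()[girdle_measurements()$group == "study", ])
tfl
#> [1] 49.2        # cm, mean of the two study animals
```

```r
trial  <- generate_trial(kinematics_template(), n_strides = 5,
                         noise_sd = 0, seed = 1)
cycles <- segment_strides(trial$series, trial$events, limb = "left_fore",
                          contralateral = "right_fore",
                          stride_lengths = trial$params$stride_length_cm)
length(filter_strides(cycles)$kept)
#> [1] 3           # realistic attrition: 2 of 5 drawn strides fall
#>                 # outside the 0.2-0.3 m/s speed band
es <- endpoint_summary(pool_strides(lapply(cycles, time_normalize)))
es[es$variable %in% c("scapula.rz", "clavicle.rx"), ]
#>       variable td_mean lo_mean contact_amplitude max_amplitude
#> 4  clavicle.rx    83.8    20.6              63.2          64.1
#> 18  scapula.rz    71.7    39.3              32.4          32.5
```

The scapula retracts from 71.7° to 39.3° over contact (32.4° contact
amplitude) and the clavicle rolls from 83.8° to 20.6° about its long axis
(63.2°) — the generator reproduces these endpoint values exactly at zero
noise, which is what the recovery tests assert.

Virtual experiments on the representative mean stride:

```r
stride <- generate_stride_kinematics(kinematics_template(), 1.50, 0.84)
suite  <- run_experiment_suite(sloth_marionette(), stride, tfl = tfl,
                               td_frame = 0)
suite[suite$axis == "cranio_caudal", c("condition", "amplitude_cm")]
#>                          condition amplitude_cm
#> 2                           normal       12.174
#> 5                no_humeral_motion        0.904
#> 8               no_scapular_motion        7.860
#> 11 no_scapular_abduction_adduction       12.184
#> 14  no_scapular_long_axis_rotation       12.658
#> 17  no_humeral_abduction_adduction       10.801
```

Muting all humeral motion collapses the cranio-caudal elbow displacement
(12.2 → 0.9 cm) and muting the scapula reduces it (→ 7.9 cm): forward
reach is driven by humeral retraction with a substantial scapular
contribution — while muting scapular abduction/adduction changes almost
nothing, mirroring the published ordering of effects.

## Package layout

* `R/transforms.R`, `R/marionette.R`, `R/pose-series.R` — kinematics core
* `R/dlt.R` — calibration, projection, triangulation, distortion grids
* `R/gait.R` — strides, filters, normalization, pooling, statistics
* `R/muting.R` — virtual experiments
* `R/morphometrics.R`, `R/reference-data.R` — measurements and published
  reference constants
* `R/synthetic.R` — the seeded generator
* `vignettes/pectoral-girdle-kinematics.Rmd` — the model, conventions,
  design decisions and limitations, in detail
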