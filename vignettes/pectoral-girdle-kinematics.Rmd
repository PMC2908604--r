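---
title: "Six-DOF pectoral girdle kinematics: models, conventions and design choices"
author: "girdlekin"
output: html_document
vignette: >
  %\VignetteIndexEntry{Six-DOF pectoral girdle kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girdlekin)
```

## The problem

During quadrupedal suspensory locomotion the two-toed sloth hangs below the
support, and the forelimb's reach is produced not by the humerus alone but
by the whole pectoral girdle: the scapula glides around the rib cage, the
clavicle constrains the shoulder's distance to the sternum, and the thorax
itself translates and yaws. Marker-free biplane x-ray motion analysis
recovers the six degrees of freedom (three translations, three rotations)
of each skeletal element by posing CT-derived bone models so that they
match the x-ray shadows in two calibrated views. `girdlekin` implements the
downstream quantitative machinery of such an analysis: the hierarchical
coordinate systems, the calibration geometry, the stride-level statistics,
and the "virtual experiments" that isolate the displacing effect of
individual motions.

The pipeline starts from digitized per-frame pose tables; matching bone
shadows to images (the interactive rotoscoping step) is out of scope, as
are CT acquisition and soft-tissue modelling.

## The kinematic model

Skeletal elements form a rooted tree — the *digital marionette*:

```
global -> thoracic_vertebra_1 -> { scapula -> humerus, clavicle }
```

Every element carries a right-handed anatomical frame placed at the centre
of rotation of the proximally adjacent joint. A six-DOF pose
$(t_x, t_y, t_z, r_x, r_y, r_z)$ maps element coordinates into the parent
frame as $p \mapsto R\,p + t + o$, where $o$ is the constant frame-origin
offset and

$$R = R_z(r_z)\, R_y(r_y)\, R_x(r_x),$$

an intrinsic x-then-y-then-z Euler sequence. The source data were posed in
an animation package whose rotate order is not recorded anywhere in the
source material; intrinsic xyz is that software's default order and is
adopted here as a *documented assumption*, not a recovered fact. The
convention string is written into every pose CSV header so data and
convention travel together. All public angles are degrees and all lengths
centimetres; radians exist only inside `euler_matrix()`.

World transforms follow by composing poses down the unique root path
(`forward_kinematics()`), and a landmark's trajectory relative to any
reference segment is
$\mathrm{world}(\mathrm{ref})^{-1} \circ \mathrm{world}(\mathrm{seg})$
applied to the landmark (`landmark_trajectory()`). Because the elbow is
expressed relative to the first thoracic vertebra, any motion of segments
at or above the vertebra cancels exactly — a property the test suite
checks by randomly perturbing the vertebra's poses.

**Euler singularity.** At $|r_y| = 90^\circ$ the x and z rotations act
about the same world axis. `euler_angles()` then returns the canonical
branch $r_x = 0$ with the full remaining rotation folded into $r_z$. The
observed kinematics stay far from this configuration; the branch matters
only for arbitrary inputs and is pinned by tests.

**Angle continuity.** Amplitudes are computed on continuous traces, so
`unwrap_deg()` removes artificial ±360° jumps; reported single angles are
reduced to $(-180, 180]$.

## Marionette geometry: what is anatomy and what is convention

The published material pins the hierarchy, the anatomical meaning of each
axis, and the study animals' segment lengths (female: scapula 8.2 cm,
humerus 15.9 cm — the defaults of `sloth_marionette()`). It does **not**
print the in-bone offsets of the joint centres or landmark coordinates,
and its frame descriptions are not fully self-consistent (the long axis is
described both as the local x-axis and as vertical — i.e. along the parent
y-axis — in the zero pose). The package therefore fixes one synthetic
convention, chosen once and used everywhere:

* the scapular centre of rotation sits at the vertebral border, with the
  glenoid at `scapula_length` along the scapular local **+y** axis (the
  bone "standing vertical" in the zero pose);
* the elbow landmark sits at `humerus_length` along the humeral local
  **+x** (long) axis from the gleno-humeral centre;
* constant frame-origin offsets within the parent (e.g. scapula at
  $(-1, 2, 3)$ cm in the vertebra frame) are nominal; they shift
  trajectories rigidly and cancel out of every amplitude.

This geometry was selected from the sign/axis alternatives the source
leaves open as the one that is anatomically defensible *and* reproduces
the qualitative physics of the published virtual experiments (humeral
muting collapses cranio-caudal elbow displacement; scapular long-axis
muting and humeral abduction partly offset each other medio-laterally).
With it, the synthetic mean stride lands close to the published normal
amplitudes (cranio-caudal 12.2 vs 14.4 cm, dorso-ventral 10.8 vs 10.3 cm,
medio-lateral 2.6 vs 2.5 cm) without any fitting.

## Biplane DLT calibration

Each x-ray view is an 11-parameter direct linear transformation from world
(cm) to image (px),

$$u = \frac{L_1 X + L_2 Y + L_3 Z + L_4}{L_9 X + L_{10} Y + L_{11} Z + 1},
\qquad
v = \frac{L_5 X + L_6 Y + L_7 Z + L_8}{L_9 X + L_{10} Y + L_{11} Z + 1},$$

solved linearly (`dlt_calibrate()`) from a 20 × 12 × 12 cm bead lattice at
1 cm spacing. World and image coordinates are centred and scaled before
the least-squares solve — standard conditioning practice the source method
does not discuss — and the coefficients are de-normalized afterwards, so
the reported RMS reprojection residual refers to real pixels. Coplanar or
collinear bead sets are rejected (the classic DLT degeneracy), as are
scenes with fewer than six beads. No nonlinear refinement is applied: on
fixture scales the linear solution already reproduces the sub-millimetre
accuracy audit (a known 15 cm separation re-measured under 0.5 px
observation noise comes back within 1 mm).

Two-view triangulation (`dlt_reconstruct()`) stacks the four DLT equations
and solves by least squares, reporting per-view reprojection residuals
rather than hiding inconsistency; near-parallel ray geometries (e.g. the
same camera twice) are rejected on conditioning.

**Distortion correction.** Image intensifiers warp the image; the
correction uses a reference grid of known lattice points and their
observed positions. `undistort()` inverts the warp cell-by-cell with an
inverse-bilinear Newton iteration; the warp model (piecewise bilinear) is
a package choice, since the source names the correction but not the
model. Points outside the warped lattice are flagged `NA`, never
extrapolated. At a 50 px lattice and realistic radial warps the
interpolation error stays below 0.1 px.

## The gait pipeline

Strides are cut at consecutive touch downs of the reference limb
(`segment_strides()`); translations are re-zeroed at each touch down,
rotations are untouched. Stride speed is stride length over cycle
duration; symmetry is the elapsed fraction of the cycle at which the
contralateral limb touches down. The inclusion filters
(`filter_strides()`) keep a stride iff speed lies in [0.2, 0.3] m/s *and*
symmetry in [0.4, 0.6]; bands are treated as closed intervals because the
source says "between" without open/closed qualification, and every
rejection is logged with its reason.

`time_normalize()` maps each stride onto 50 evenly spaced samples over the
contact phase and 50 over the swing phase. Sample 1 is touch down, sample
50 lift off, sample 100 the next touch down, and those endpoint values are
preserved exactly — crucial because the published endpoint table is defined
at these instants. `pool_strides()` takes pointwise means and (n−1)
standard deviations across trials, and `endpoint_summary()` derives the
published table's arithmetic: contact amplitude is |lift-off − touch-down|
of the *mean* trace (this reproduces the printed rotation rows within
last-digit rounding; the printed table itself shows one row, 16.2 vs 16.1,
where amplitudes were evidently computed before rounding the endpoint
means), and maximal amplitude is max − min of the mean trace over the full
100-sample cycle. The full-cycle window is a package decision: printed
maximal amplitudes exceed contact amplitudes, and the published curves
span the whole cycle, but the window is never stated.

Between-individual comparisons use the classic equal-variance two-sample
t-test (`compare_individuals()`, delegating to `stats::t.test`), matching
the published analysis; the degenerate zero-variance/equal-means case
returns p = 1 by convention. `repeatability_summary()` summarizes repeated
digitizations of one frame and motivates the 0.1 cm / 0.1° reporting
precision used throughout.

## Virtual experiments

`apply_muting()` holds selected DOFs of a segment at their touch-down
value from touch down onward. Holding the *touch-down* value — not zero —
is forced by the requirement that the initial elbow position be identical
across conditions; the test suite asserts that every condition's
trajectory starts at exactly the normal trajectory's touch-down point.
Muting is idempotent and a no-op on DOFs already constant at their
touch-down value.

The six canonical conditions (`muting_conditions()`) are: normal, total
humeral muting, total scapular muting, scapular abduction/adduction only,
scapular long-axis rotation only, humeral abduction/adduction only.
`run_experiment_suite()` evaluates all of them on one representative
series — the pooled mean stride, matching the published "normal locomotion
(mean)" row — and reports per-axis max/min/amplitude plus amplitude as a
percentage of total forelimb length (tfl). The reported anatomical axes
map onto the vertebral frame as cranio-caudal = x, dorso-ventral = y,
medio-lateral = z; the mapping is stated here and in the function
documentation because the source never says which world axis is which in
its displacement table.

**tfl.** The normalization constant is never defined in the source; the
reading adopted here — mean over the two study animals of scapula +
humerus + ulna + hand length, giving 49.2 cm — reproduces 17 of the 18
printed %tfl entries to the last digit. The single exception (printed
30.1 where 15.2/49.2 = 30.9) is carried verbatim in
`elbow_displacement_reference()` and documented as a misprint rather than
silently corrected.

## The synthetic-data generator

No raw recordings are deposited, so every stage is exercised on synthetic
trials. `kinematics_template()` encodes, per segment and DOF, the
published touch-down and lift-off endpoint values, plus mid-phase knots
anchored in the qualitative stride description: scapular retraction onset
at ~30% of contact, the caudal scapular-translation peak of ~−0.8 cm in
the second half of contact, humeral full flexion of ~−125° shortly after
mid contact, and the return to full protraction/extension shortly before
the next touch down. Everything beyond these anchors — in particular the
exact shapes between knots — is synthetic convention.

Traces are monotone-segment piecewise cubics (Fritsch–Carlson, via
`stats::splinefun(method = "monoH.FC")`) through the knots, evaluated on
an integer frame grid whose touch-down, lift-off and cycle-end frames
coincide with knots, so generated endpoints are *exact* — which is what
lets the end-to-end recovery tests assert exact equality at zero noise.
Fourier fits were rejected because they trade endpoint control for
smoothness the tests do not need. The curve is C¹ within the stride;
periodic continuity of the derivative across strides is not enforced.

`generate_trial()` draws per-stride contact and swing durations and stride
lengths from truncated normals (±3 s.d., matching the published pooled
means 1.50 ± 0.2 s, 0.84 ± 0.2 s, 58.9 ± 5.0 cm — so drawn speeds straddle
the 0.2–0.3 m/s inclusion band realistically), symmetry uniformly inside
[0.4, 0.6], and adds per-frame Gaussian digitization noise at the
published repeatability magnitudes (0.13/0.12/0.12 cm, 0.76/0.24/0.16°)
by default. All randomness flows through the single seed argument.
`generate_calibration_scene()` builds the bead lattice and two synthetic
pinhole views in the biplane geometry (1536 × 1024 px sensors, orthogonal
latero-lateral and dorso-ventral axes) and returns ground-truth cameras
for oracle tests.

**What the generator does not emulate.** Real digitization error is
neither white nor Gaussian (it correlates across frames and with bone
visibility); real strides vary in shape, not only in duration and
amplitude endpoints; x-ray distortion, bead mis-detection and rotoscoping
bias are absent. Passing tests therefore demonstrate that the *pipeline
arithmetic* is correct and recoverable under the published noise
magnitudes — not that the biological conclusions would survive worse
data.

## Numerical choices

* Rigid-transform validation: orthonormality and unit determinant to
  1e−8; composition chains agree with a homogeneous-matrix oracle to
  1e−10, forward kinematics to 1e−9 cm.
* Euler round trips hold to 1e−8 degrees away from the singularity;
  random-triple sampling in tests keeps $|r_y| \le 85^\circ$.
* DLT: normalized linear solve; noiseless round trips to 1e−8 px/cm;
  degeneracy detected via the smallest singular value of the centred bead
  cloud (relative threshold 1e−8) and the R-diagonal ratio of the stacked
  triangulation system (1e−10).
* Time normalization uses linear interpolation within sub-phases; interior
  gaps are bridged linearly. Sub-phases need at least 2 samples.
* Rounding: presentation values round half-even via R's `round()` (means
  and s.d.s to 2 decimals in morphometric summaries, 0.1 in repeatability
  reports, %tfl to one decimal); all arithmetic happens unrounded.

## Problem sizes used by tests and the acceptance script

Property suites run 30–1000 random cases per invariant; synthetic trials
use 2–20 strides at 300 fps (~700 frames each); the law-of-large-numbers
check uses 200 strides; calibration scenes use the full 3549-bead lattice.
These sizes were chosen so the whole suite completes in about a minute
while leaving Monte-Carlo bounds comfortably tight.

## Known limitations

* The Euler order is an assumption (recorded in file headers), and all
  in-bone joint-centre offsets are fixture conventions; absolute
  trajectory *positions* from `sloth_marionette()` are therefore nominal
  even though amplitudes are meaningful.
* Full published trajectories (the per-frame curves and the displacement
  table's absolute max/min values) are not reproducible without the raw
  recordings; the package reproduces the in-table arithmetic exactly and
  the virtual-experiment *orderings* on synthetic data.
* The distortion model is piecewise bilinear; strongly non-monotone warps
  that fold a grid cell would defeat the inverse iteration (flagged, not
  silently accepted).
* Pooling across individuals is statistically justified here by
  non-significant t-tests at n = 14/18; the pipeline exposes the test but
  does not gate pooling automatically.
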