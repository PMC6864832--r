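---
title: "Measuring a driver's gaze range from eye and head angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring a driver's gaze range from eye and head angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazerange)
```

## The measurement problem

A driver redirects gaze by rotating the eyes *and* the head together
(eye-head coordinated movement). A wearable eye tracker reports only the
eye-in-head angle; to know where the driver is looking in vehicle
coordinates, the head angle must be measured too, and in a moving car
there is no room for external depth sensors. `gazerange` implements an
offline pipeline around a single wearable device: the head angle is read
from the device's forward-facing *view camera* by tracking four printed
markers on the windshield, and the gaze signal is the sum

$$E(t) = f_1(t) + f_2(t),$$

where $f_1$ is the eye-in-head angle (an input CSV, produced by the
tracker's own pupil processing) and $f_2$ the head angle estimated here.
Each gaze sample is classified into one of nine cabin zones, and a
whole session is condensed into the *gaze range*: the product
$X \times Y$ of the axis-wise spans of the gaze histogram, a scalar
summary of how widely the driver scanned the scene. Narrow gaze ranges
are the quantity of interest when screening drivers (for example,
elderly drivers, whose effective field of view is the factor most
associated with crash risk).

## Head pose from marker displacements

**Geometry.** The view camera is modelled linearly: a marker
displacement of one full frame width corresponds to the full horizontal
viewing angle, so

$$\text{angle} = \text{displacement (px)} \times \frac{\mathrm{fov}}{\text{resolution}} .$$

Resolution and viewing angles are mandatory config inputs
(`camera_model()`), not constants: they are properties of the recording
hardware. The example config uses 640x480 px and 80x60 degrees; the
synthetic scene uses 320x240 px at the same angles (4 px/degree). No
lens-distortion or perspective term is modelled; within the +-30 degree
working range of the method the linear model is the method's own
assumption, and the synthetic forward model mirrors it exactly so that
estimator tests are tests of the estimation logic, not of model
mismatch.

**Calibration.** The driver faces forward for a few seconds. Markers
1-3 are detected in every calibration frame and each marker's reference
position is the per-frame *median* (robust against isolated
mismatches; the choice matters little on clean frames and protects the
reference against a single false match). The fourth (star) marker
extends the measurable range but is off-screen in the forward pose, so
its reference x is extrapolated collinearly from the Marker2/Marker3
references using the physical spacing ratio $\alpha:\beta$:
$C_x = -\tfrac{1}{\alpha}\{\beta(A_x-B_x) - \alpha B_x\}$, the unique
point such that B divides A-C in ratio $\alpha:\beta$. The formula is
orientation-free, so mirrored camera layouts work unchanged. Its
reference y is Marker3's (the markers sit on one rail).

**Roll correction.** Yaw and pitch are read from marker displacements,
but a tilted head (roll $\theta$) displaces markers even at zero
yaw/pitch. With two markers visible, $\theta$ is the angle of the line
joining them, $\theta = \arctan\{(y_2-y_1)/(x_2-x_1)\}$, minus the same
pair's reference baseline angle (zero for rail-mounted markers). Each
detection is then rotated by $-\theta$ about the image centre before
displacements are taken. Two deliberate choices here:

* *Pivot.* Camera roll rotates the whole image about its centre, so the
  centre is the natural pivot; for displacement differences any fixed
  pivot is equivalent.
* *References are not rotated.* They were recorded at zero roll; undoing
  the current frame's roll maps detections back into that zero-roll
  frame. Rotating the references too would leave a residual error of
  about $2\sin(\theta/2)\,\lVert \mathrm{ref}-c\rVert$ pixels, which at
  $\theta=30^\circ$ is several degrees -- the package's roll-invariance
  tests (yaw/pitch within 1 degree of the roll-free estimate for
  $|\theta| < 30^\circ$) only hold with the references fixed.

With fewer than two markers the last valid roll is carried (0 before
any), trading a possibly stale roll for continuing single-marker
operation.

**Axis selection.** Displacement-to-angle conversion is most accurate
near the optical centre, so yaw is read from the (corrected) marker
whose x is nearest the image x-centre and pitch from the one nearest
the y-centre; ties break to the lower marker id so the choice is
deterministic. No smoothing is applied at marker hand-off frames: on
clean geometry the per-marker estimates coincide, and smoothing would
blur genuine head motion.

**Missing markers.** A frame with no accepted detection yields an
*invalid* pose. Invalid poses propagate to invalid gaze samples and are
excluded from histograms; interpolating them would fabricate gaze data.

## Template matching and the search planner

Markers are located by zero-normalised cross-correlation (NCC) on
grayscale, scored in $[0,1]$ (negative correlations clamp to 0; flat
windows score 0), accepted above a configurable
`similarity_threshold`. The default 0.70 accepts clean renders (score
about 1) and survives moderate pixel noise while rejecting
structureless background; it is deliberately conservative because a
false marker position corrupts the pose silently, whereas a missed
frame is only an invalid sample.

Searching every marker over every frame is wasteful, so the tracker
prunes the search space using three ideas, all consequences of the
fixed left-to-right marker layout (1, 2, 3, 4) and of motion
continuity:

1. **Ordering constraints.** Each marker lies strictly right of its
   left-hand neighbours and strictly left of its right-hand ones
   (bounds taken from markers already found this frame, else from the
   previous frame). Marker4 sits far enough out that it can never share
   a frame with Marker1 or Marker2; the exclusion is applied in both
   directions (4 skipped when 1/2 present, 1/2 skipped right after 4
   was seen). Without the symmetric form, every marker that is
   currently out of view costs a futile full-frame scan per frame,
   which dominates runtime.
2. **Tracking windows.** A marker seen at $t-1$ is searched in a window
   of half-width `search$margin` (default 48 px) around its last
   position, grown along the $t\!-\!2 \to t\!-\!1$ displacement vector by
   `extension_gain` (default 1.5) times the displacement -- enough to
   cover constant-velocity head sweeps with a 50% margin.
3. **Sectioning.** Drivers rarely pitch far, so each region is cut into
   three horizontal bands searched centre-first, each band expanded
   vertically by (template height - 1) px so a marker straddling a band
   boundary is still wholly inside one band. The first band whose best
   score clears the threshold wins.

Markers are always searched in the fixed order 1, 2, 3, 4, making the
whole per-frame search deterministic.

## Gaze fusion and zone classification

Fusion is exact componentwise addition; there is nothing to tune. Eye
samples are aligned to frame times by nearest neighbour within half a
frame interval -- beyond that the streams simply do not overlap and an
alignment error is raised rather than extrapolating.

The nine zone labels (front, rearview mirror, meter, right mirror,
right, right back, left mirror, left, left back) carry no geometry of
their own, so the default map is a convention, chosen to reproduce the
left/right/front judgments of the bundled on-road log: front is
$|x| \le 20^\circ$, left/right beyond that, the "back" variants beyond
$\pm 90^\circ$, and the mirror/meter zones are small open rectangles
(rearview above centre, meter below centre, side mirrors low-left and
low-right). Matching is first-match-wins over an ordered table with the
specific rectangles first; rectangle interiors are open, so boundary
points fall through to the band rows and receive the more central
label. The whole map is replaceable via the config `zones` block, and
the partition property (every finite point gets exactly one label) is
tested on a dense grid.

## The gaze-range statistic

Valid gaze samples are binned on a `bin_width`-degree grid (default 5;
half-open bins, edge samples go up). Two summaries are computed:

* **Peak-relative threshold rule** (the headline statistic): marginal
  counts per axis; bins with at least `range_threshold` (default 0.05)
  of the peak marginal count survive; $X_{\min}/X_{\max}$ are the outer
  edges of the surviving x-bins, $X = X_{\max}-X_{\min}$, likewise $Y$,
  area $= X \times Y$. Reading the 5% cut as *relative to the peak*
  makes the statistic scale-invariant (session length drops out) and
  always well-defined (the peak bin survives). The marginal (per-axis)
  reading is used because X and Y are defined axis-wise; a joint-2-D or
  fitted-density reading would change only the constant, and the
  threshold is configurable.
* **Gaussian fit**: per-axis mean and SD with the 95% interval
  $\mu \pm 1.96\sigma$, the smooth companion used for cross-checking.

For truly Gaussian gaze the marginal falls to 5% of its peak at
$\sigma\sqrt{2\ln 20} \approx 2.448\sigma$, so $X \to 2 \times 2.448
\sigma$ for fine bins; the package's recovery tests use this closed
form (within 10% at $n = 5000$, bin $\le \sigma/2$). Bin width trades
resolution against count noise: the default 5 degrees suits session
spreads of $\sigma \gtrsim 10^\circ$; tests that check the closed form
at $\sigma_y = 8^\circ$ use 4-degree bins to stay at or under
$\sigma/2$.

`compare_subjects()` tabulates X, Y and area per subject with the
ratio to a designated reference subject (e.g. a driving instructor) and
flags areas below a configurable fraction (default 0.5) of the
reference. It ranks and flags only; clinical pass/fail scoring is
explicitly out of scope.

## The synthetic scene: what it does and does not emulate

`simulate_session()` renders frames under a known head trajectory:
anti-aliased marker glyphs displaced by the *same* linear camera model
the estimator assumes and rotated by roll about the image centre, over
a uniform or seeded-noise background; plus an eye stream defined as
sampled gaze minus head angles, so fusing it with the true head angles
reproduces the sampled gaze distribution identically. The gaze model is
saccade-and-hold: a new 2-D Gaussian target with per-frame probability
`saccade_rate` (default 0.3, roughly one saccade per 0.3 s at 10
frames/s), held otherwise.

Default study conditions, chosen once: 320x240 px camera at 80x60
degrees, 17 px glyphs, marker anchors x = 40, 120, 200, 360 on one rail
(star off-screen when facing forward; $\alpha:\beta = 1:2$), yaw
amplitude 25 degrees with smaller pitch/roll, gaze spread
$\sigma = (15, 8)$ degrees. Everything is reproducible bit-for-bit from
a seed.

Passing tests on this generator show that the estimator inverts its own
geometry to well under a degree (rounding to integer draw positions
costs at most about 0.2 degrees at 4 px/degree) and that the
statistics pipeline recovers known distributions. They deliberately do
*not* show robustness to what real recordings add: perspective and lens
distortion, motion blur, illumination changes, template shape change
during fast head motion (the dominant failure mode of the matcher on
the road), vibration, or eye-tracker noise. Field-scale accuracy
figures therefore cannot be reproduced at desk scale; the bundled
validation tables record them, and the test suite substitutes
property-based checks (pose recovery, oracle equivalence, roll
invariance, closed-form range recovery).

## Numerical and degenerate-input choices

* Coordinates are 0-based pixels, origin top-left, y downward; regions
  half-open; a detection's anchor is the template's top-left.
* NCC ties resolve to the smallest y then smallest x; compiled scan and
  the brute-force R oracle agree to 1e-9.
* Two detections sharing an x-column make roll undefined: a
  degenerate-geometry error, not a guess.
* Zero-variance sessions refuse a Gaussian fit; empty sessions refuse a
  histogram. Schema violations in CSV/config input raise typed errors
  (`gr_schema_error`, `gr_parse_error`, `gr_config_error`,
  `gr_calibration_error`), which the CLI maps to exit codes 2/3.
* Eye angles are validated against the tracker's physical +-180 degree
  range at load time.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: the rendered
end-to-end recovery runs 1500 frames; the closed-form gaze-range
recovery uses 5000 Gaussian samples without rendering; pose-recovery
grids use 20 poses (noiseless and noisy); oracle-equivalence uses 50
seeded fixtures.

## Known limitations

* The linear camera model ignores perspective; accuracy degrades as
  markers approach the frame edge under large combined rotations.
* Roll is estimated from detection pairs of possibly different marker
  shapes; with only one marker visible the roll is carried, not
  measured.
* The matcher is not scale- or rotation-invariant by design; glyphs are
  matched upright, which bounds usable roll in real recordings well
  before the geometric correction does.
* The zone map defaults encode one vehicle's geometry; different
  cockpit layouts need their own `zones` block.
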