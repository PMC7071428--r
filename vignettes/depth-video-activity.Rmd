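---
title: "Estimating children's physical activity intensity from 3D video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating children's physical activity intensity from 3D video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Wearable accelerometers are the standard instrument for quantifying young
children's physical activity, but attaching sensors to 2--5-year-olds is
burdensome and limits what can be observed about context. A consumer 3D
camera (infrared + depth, 640 x 480 px at 30 Hz) records the same indoor
play session without instrumenting the child: infrared pixel intensities
carry the mediolateral (x) and vertical (y) motion, and the depth stream —
whose pixel values are sensor-to-object distances in millimetres — carries
the anteroposterior (z) motion. `depthPA` turns such recordings into
accelerometry-style triaxial vector-magnitude (VM) signals in 5-second
epochs, and calibrates/validates single-feature decision-tree classifiers
of activity intensity (sedentary SED, light LPA, moderate-to-vigorous
MVPA) against second-by-second direct-observation coding (CARS).

Because no public recordings of this kind exist, the package includes a
first-class synthetic renderer (`renderSequence()`): scripted shapes move
through infrared/depth frame pairs with exact ground truth (per-frame
centroids, per-second velocities per plane, CARS-consistent activity
codes). All validation in the test suite and acceptance script runs
against that renderer.

# The processing chain

## Segmentation

Moving objects are found by frame differencing: a pixel is foreground
when consecutive infrared frames differ by more than `pixel_threshold`
(default 1400 intensity units). Frames with more than
`frame_threshold = 14000` foreground pixels are declared unevaluable
(sensor flicker) and skipped. The binary difference mask is then cleaned
by a fixed morphological cascade:

1. Sobel edge enhancement in both directions (binarised at > 0; the frame
   border is replicate-padded so the image boundary itself is never an
   edge);
2. a 3 x 3 majority fill (output 1 iff the neighbourhood sum exceeds 5);
3. morphological closing with a disk of radius 9 px;
4. binary reconstruction using the closed image as marker and the
   difference mask as mask (for binary images this keeps exactly the mask
   components touching the marker);
5. geodesic dilation with a 25 px square element, merging fragments of
   one object into a single connected component;
6. 8-connected hole filling; and
7. one thinning pass (a single Zhang--Suen iteration) to shave residual
   single-pixel noise. Thinning is deliberately *not* iterated to a
   skeleton: its purpose here is noise reduction, and a skeleton would
   drop solid blobs below the component-size floor.

Connected components smaller than `min_component = 375` px are discarded
(the rule is *keep iff >= 375*: the removal sentence is the operative
one). Survivors become blobs with centroid (arithmetic mean of member
pixels, 0-based coordinates) and tight bounding box.

A note on the two thresholds: the per-pixel difference threshold (1400)
and the per-frame foreground-count threshold (14 000) are distinct
quantities that are easy to conflate typographically; both are
config-exposed (`pixel_threshold`, `frame_threshold`).

## Tracking

Blobs are associated across frames by greedy nearest-centroid matching
against Kalman-predicted positions, gated at `gate_px = 50` px/frame
(comfortably above the fastest expected child at the nearest calibrated
depth). Unmatched blobs open new numeric identities; tracks unmatched for
more than `max_misses = 15` frames close. Each track runs a
constant-velocity Kalman filter (process noise 1 px^2, measurement noise
4 px^2, initial covariance 100 x I). These association and filter
constants are engineering choices — the procedure they implement is
standard — and all are config-exposed. Person identity is resolved by a
reviewed whitelist of track ids (`selectChildTracks()`); there is no
automatic re-identification.

The depth reading attached to each track entry comes from a growing
window search around the centroid (3 x 3, 5 x 5, ... up to
`depth_window = 21` px), returning the nonzero depth nearest the centroid
— the depth sensor cannot quantise objects flush against a wall, so the
centroid pixel itself often reads 0. A frame with no reading inside the
maximum window contributes a missing depth.

## Metric calibration

An object of known height (1.75 m) observed at several depths yields
scale values (metres per pixel); ordinary least squares of scale on depth
gives

$$\mathrm{m/pixel}(d) = a \cdot d_{\mathrm{mm}} + b,$$

with canonical coefficients $a = 1.5\times10^{-6}$ and
$b = 6.4\times10^{-4}$ for the geometry the renderer emulates.
`fitCalibration()` recovers generating coefficients to machine precision
on noiseless observations (this is one of the acceptance checks).

## Fourier velocity estimation

For each 1-second window of $K = 30$ frames, the centroid intensity is
placed at its own coordinate in a zeroed 1-D projection array (length 640
for x, 480 for y, millimetre bins for z). Multiplying that array
elementwise by $\exp(i\,2\pi a_1 q\,\Delta t)$ (with $q$ the array
position and $\Delta t$ the inter-frame interval) and summing collapses
each frame to a single complex sample
$s_k = I_k e^{i 2\pi a_1 q_k \Delta t}$: a constant-velocity object
produces a complex tone whose frequency is proportional to its velocity.

The scale constant is $a_1 = K / v_{\max}$ with $v_{\max}$ *expressed in
axis units per frame* (pixels per frame for x/y, mm per frame for z,
derived from the expected maxima of 4 m/s in x and z and 2.8 m/s in y via
the calibration at the observed depth). This choice makes the expected
velocity range sweep the $K$ spectral bins exactly once, so the first
peak of the FFT magnitude spectrum locates the velocity; expressing
$v_{\max}$ in other units either aliases ordinary child movement many
times over or collapses the whole range into the DC bin, and neither can
produce the frequency--velocity peak this construction relies on.

Two numerical refinements matter:

* **Sub-bin accuracy.** A 30-point spectrum quantises velocity to
  $v_{\max}/30$ per bin. The per-frame phase increments
  $\arg(s_{k+1}\bar s_k)$ are therefore averaged (after unwrapping, see
  below) — the standard single-tone frequency refinement — which brings
  the estimator within a fraction of a pixel per second of a
  finite-difference oracle on reversal-free windows.
* **Direction.** A complex tone's phase increment is only known modulo
  $2\pi$, so speed alone cannot distinguish a fast positive motion from
  a slow negative one. The net drift of the projected coordinate across
  the window selects each increment's $2\pi$ branch, resolving both sign
  and magnitude over the full $\pm v_{\max}$ range. (A sign rule based on
  curvature-sign agreement of the real and imaginary parts was
  considered and rejected: on a rotating phasor its answer is independent
  of rotation direction.)

Windows with more than half of their frames unevaluable yield missing
samples. x/y velocities convert to m/s through the calibration at the
window's median depth; z velocities are already metric (mm/s / 1000) —
applying a per-depth pixel scale to an axis already measured in
millimetres would be dimensionally wrong, so the Eq-style scaling applies
to the pixel planes only. Estimates are clipped at the plane maxima with
a warning.

By default the Fourier stage consumes the *raw* blob centroids rather
than the Kalman-smoothed ones (`use_smoothed = FALSE`): on noiseless
input the raw centroids are already quantisation-limited, while the
filter's transient after a direction reversal leaks into the adjacent
window. The smoothed stream remains available and config-selectable for
noisy recordings.

## Accelerations, VM, epochs

Per-second velocities difference to accelerations in g
($a_t = (v_t - v_{t-1}) / \Delta t / 9.80665$; first sample 0; gaps
propagate). Per second, $VM = \sqrt{a_x^2+a_y^2+a_z^2}\times 1000$;
non-overlapping 5-s bins aggregate by the mean of available seconds
(config: mean or sum — the mean is robust to missing seconds, which is
why it is the default), and epochs with 3+ missing seconds are missing.
No gravity component is subtracted: the camera measures displacement,
not specific force.

## CARS ground truth

Second-by-second codes (1 lying/sitting, 2 standing, 3 walking,
4 running/jumping, 5 not in frame) reintegrate into 5-s epochs by
frequency-weighted averaging — algebraically the arithmetic mean of the
scored seconds. Code-5 seconds drop out of the denominator; an epoch that
is all code 5 is missing. Cut points: SED < 2, LPA 2--2.99, MVPA >= 3
(score exactly 3 is MVPA). Inter-rater reliability uses ICC(2,1)
(two-way random effects, absolute agreement, single measure) — the
stricter conventional choice for coder reliability, computed from the
ANOVA mean squares.

## Classification and equivalence

The VM epoch value is the *sole* feature. `trainIntensityModel()` grows
Gini CART trees via `rpart` (cp = 0, no pruning, `min_leaf = 20` epochs,
max depth 8 — unstated in the protocol being emulated, so fixed here and
config-exposed) in two modes: one-vs-all (three binary trees: each class
against the other two combined) and multiclass. Evaluation reports
per-class one-vs-rest AUC from leaf posterior scores (rank statistic,
ties half-credit), percentile-bootstrap 95% CIs over epoch resampling,
and sensitivity/specificity at hard labels; multiclass models add the
confusion matrix. The default protocol is resubstitution (train and
evaluate on the same epochs), matching the calibration-study setting; a
consequence worth stating plainly is that an unpruned tree's
resubstitution AUC is optimistic, so chance-level sanity checks
(label permutations) are run out-of-sample, where the AUC correctly sits
at 0.5.

Observed vs estimated per-child time shares (% of valid epochs per
class; epochs missing in either source leave both denominators) are
compared by median differences with percentile-bootstrap 90% CIs (2000
resamples, seeded) and nonparametric TOST: two one-sided exact Wilcoxon
signed-rank tests of the median paired difference against $\pm\Delta$
($\Delta$ = 10 and 20 percentage points), $p = \max$ of the two
one-sided p-values, equivalence declared at $\alpha = 0.05$. A sign-test
variant is available. Negative median differences mean underestimation.
When every shifted difference is tied the signed-rank p-value comes from
the tie-corrected normal approximation (exact enumeration is undefined
under ties), which saturates just below 1 in the all-outside-the-margin
case.

# What the synthetic data emulate — and what they do not

`renderSequence()` reproduces the features the pipeline is sensitive to:
16-bit quantisation, rounded-millisecond timestamps, integral (rasterised)
object positions, additive Gaussian infrared noise, a constant far-plane
depth background with per-object depth values, and depth dropouts (zero
readings) over scripted spans. `simulateStudy()` generates the epoch
level directly: 10 children x 60 epochs (the 5-minute analysis window at
5-s epochs), cohort class proportions SED/LPA/MVPA = 0.28/0.41/0.31
jittered per child (Dirichlet draw), and class-conditional lognormal VM
values (geometric means 15/60/200 VM units, common log-sd 0.5) whose
adjacent-class overlap sits near 10% — moderate, deliberately below 15%.

Not emulated: structured-light depth noise, perspective scaling of
object size with depth, occlusion between persons, non-rigid motion, and
illumination change. Passing tests therefore demonstrate correctness of
the algorithms under controlled conditions, not field accuracy on real
children; the renderer's constant-intensity rigid shapes are an easier
segmentation target than a moving child.

Fixture geometry: validation fixtures use a narrow slab (24 px along the
motion axis) so that the leading and trailing difference strips always
merge into a single component under the 25-px geodesic dilation,
whatever the speed; pure-z scripts additionally drift slowly in x
because depth change alone is invisible to the infrared differencing (a
real child moving in depth always moves in the image plane too).
Problem sizes throughout (4-s velocity fixtures, 600-epoch studies,
2000-replicate bootstraps) were chosen as the smallest at which the
checked properties are stable.

# Degenerate inputs and tie-breaks

* Empty difference mask -> no blobs; unevaluable frames are skipped, not
  retried against a different reference frame.
* Depth search ties break by Euclidean distance, then raster order.
* Component labels are assigned in raster-scan order of first occurrence,
  making outputs byte-reproducible.
* Association conflicts resolve greedily by smallest distance.
* All-code-5 CARS epochs, children with zero valid epochs, single-class
  training data, and zero-variance ICC inputs raise warnings/errors
  rather than producing numbers.

# Known limitations

* The velocity estimator assumes approximately constant velocity within
  each 1-s window; direction reversals inside a window bias that window
  toward the dominant leg.
* Epoch aggregation defaults to the mean; the sum variant changes the VM
  scale by 5x and would require re-deriving classifier cut points.
* Resubstitution evaluation matches the emulated calibration protocol
  but overstates generalisation; a leave-one-child-out evaluation can be
  assembled from the exported pieces (`trainIntensityModel` /
  `evaluateIntensityModel` on per-child splits).
* The .k3dv container is this package's own interchange format, not a
  decoder for any camera vendor's dump format.
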