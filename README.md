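# depthPA

Physical-activity intensity estimation for young children from 3D
(infrared + depth) video, without wearable sensors.

A consumer depth camera records an indoor play session as paired 640 x 480
16-bit infrared and depth frames at 30 Hz (depth pixel values are
sensor-to-object distances in millimetres; 0 means no reading). `depthPA`
converts such recordings into accelerometry-style triaxial acceleration
vector-magnitude (VM) signals and classifies 5-second epochs into
sedentary (SED), light (LPA) and moderate-to-vigorous (MVPA) physical
activity against direct-observation ground truth. It is aimed at
physical-activity measurement researchers who want to calibrate and
validate camera-based intensity estimation at desk scale.

## The method

1. **Segmentation** — frame differencing between consecutive infrared
   frames (`|f_i - f_j| > 1400`; frames with more than *T* = 14 000
   foreground pixels are unevaluable), then Sobel edge enhancement, a
   3x3 majority fill, closing (disk *r* = 9), binary reconstruction
   against the difference mask, geodesic dilation (25 px square), hole
   filling, one thinning pass, and removal of components below 375 px.
2. **Tracking** — nearest-centroid association (gate 50 px/frame) with
   per-track constant-velocity Kalman smoothing, persistent numeric
   identities, a reviewed whitelist to select the child's tracks, and a
   growing-window (up to 21 x 21) depth lookup at each centroid.
3. **Metric calibration** — least squares of scale on depth for an
   object of known height: `m/pixel = 1.5e-6 * depth_mm + 6.4e-4`.
4. **Fourier motion analysis** — per 1-s window of K = 30 frames, the
   centroid intensity is projected onto a 1-D array and transformed by
   `exp(i 2π a₁ q Δt)` with `a₁ = K / v_max` (v_max in axis units per
   frame; 4 m/s for x/z, 2.8 m/s for y); the spectral peak, refined by
   the phase of the lag-1 autocovariance, gives the signed velocity.
5. **VM epochs** — per-second accelerations in g, `VM =
   sqrt(ax² + ay² + az²) × 1000`, aggregated over 5-s epochs.
6. **CARS ground truth** — second-by-second activity codes (1–5)
   reintegrated by frequency-weighted averaging; cut points SED < 2,
   LPA 2–2.99, MVPA ≥ 3; inter-rater ICC(2,1).
7. **Classification & equivalence** — one-vs-all CART and multiclass
   CART (rpart, Gini, VM as the sole feature), per-class AUC with
   bootstrap 95% CIs, sensitivity/specificity, and nonparametric TOST
   (paired Wilcoxon signed-rank) on observed vs estimated per-child
   time shares at Δ = 10% and 20%.

Because no public 3D play-session recordings exist, the package ships a
synthetic renderer (`renderSequence`) that draws scripted moving shapes
into infrared/depth frame pairs with exact ground truth, plus an
epoch-level study simulator (`simulateStudy`). The methods vignette
(`vignettes/depth-video-activity.Rmd`) documents every model choice,
parameter and limitation.

## Worked example

Render a child-sized slab moving at 1.2 m/s, run the full chain, and
recover its velocity:

```r
library(depthPA)
sc  <- makeConstantVelocityScript(1.2, "x", depth_mm = 3000, duration_s = 4)
ren <- renderSequence(sc, duration_s = 4, noise_sd = 0, seed = 1)
tracks <- extractTracks(ren$frames)
tracks
#> TrackSet: 1 track(s)
#>   track 1: 119 frame(s), first seen 33 ms
vel <- trackVelocities(selectChildTracks(tracks, "1"))
subset(vel, plane == "x")
#>    second plane v_axis_per_s     v_mps depth_mm n_valid
#> 1       1     x     233.4047  1.199700     3000      29
#> 4       2     x    -225.4395 -1.158759     3000      30
#> 7       3     x     225.4395  1.158759     3000      30
#> 10      4     x    -225.4395 -1.158759     3000      30
```

The scripted 1.2 m/s back-and-forth motion is recovered within 3.5% each
second (signs alternate with the direction legs; `v_axis_per_s` is the
pixel displacement per 30 frames before metric scaling).

Classify a simulated 10-child study (600 labelled epochs) and test
equivalence of observed vs estimated time use:

```r
st   <- simulateStudy(nChildren = 10, epochsPerChild = 60, seed = 1)
cart <- trainIntensityModel(st, "onevsall")
evaluateIntensityModel(cart, st, nBoot = 2000, seed = 1)
#> EvaluationReport
#>  class   auc ci_low ci_high sensitivity specificity n_pos n_neg
#>    SED 0.937  0.912   0.960       0.908       0.966   163   437
#>    LPA 0.865  0.835   0.893       0.815       0.882   254   346
#>   MVPA 0.891  0.861   0.917       0.858       0.923   183   417
sh <- timeShares(st, transform(st, intensity = predictLabels(cart, st$vm_value)))
equivalenceAnalysis(sh, deltas = 20, nBoot = 2000, seed = 1)
#>   class delta median_difference  ci90_low ci90_high     p_value equivalent  n
#> 1   SED    20                 0 -1.666667 1.6666667 0.002912512       TRUE 10
#> 2   LPA    20                 0 -4.166667 0.8333333 0.002896523       TRUE 10
#> 3  MVPA    20                 0 -3.333333 5.8333333 0.002928550       TRUE 10
```

AUCs per class sit in the high 0.8s–0.9s under the generator's moderate
class overlap, and the estimated per-child percentages of time are
statistically equivalent to the observed ones within a 20-point margin
(p < 0.05 for all three classes).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/depthpa.R simulate --preset walk --duration 10 \
    --seed 7 --out runs/walk
Rscript inst/scripts/depthpa.R all --preset mixed --duration 60 --out runs/full
```

Exit codes: 0 ok, 1 runtime error, 2 usage error. Every run writes a
`config.txt` snapshot of all tunables and a `run_log.txt` with versions
and the seed.

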