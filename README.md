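# lightfuse

Light-adaptive fusion of human keypoint streams for movement analysis and
rehabilitation biomechanics.

## The problem

Two affordable ways of tracking limb joints fail in complementary ways: a
depth camera's skeletal tracker is immune to lighting but jitters spatially
(worst at the knees and ankles during leg motion), while an RGB pose
detector is stable during motion but falls apart as the scene darkens.
`lightfuse` blends the two streams into one that adapts to illumination:

1. **Align** — the depth stream `V` is mapped into the RGB stream's
   coordinate system by a rigid transform `V' = R V + T`; a pinhole model
   projects 3-D joints to pixels for evaluation.
2. **Relight** — an illumination simulator darkens sRGB images with a
   highlight-preserving inverse gain
   `f(g) = max(x·g, (1−α)·x·g + α·g)`, `α = (max(x−t,0)/(1−t))²`,
   applied in linear light with the standard piecewise gamma curve.
3. **Calibrate** — per lighting condition, the fusion weight `h` of
   `L = h·U' + (1−h)·V'` is solved by L-BFGS to minimize the mean squared
   error against motion-capture reference data `D`; a logistic law
   `h_est = 1/(1 + e^(−a·x̄ + b))` is then fitted to the (brightness,
   optimal weight) pairs across the sweep.
4. **Fuse & smooth** — new frames are fused with the weight predicted from
   scene brightness and smoothed by a per-joint constant-velocity Kalman
   filter (`Q = 0.08·I`, `R = 0.2·I`).
5. **Evaluate** — MSE, R², cosine similarity, percentage difference,
   PCK-style joint accuracy at 6/8 px thresholds, coefficient of
   variation, plus global SSIM and PSNR for relit-image validation.

Because no recordings are deposited with the original study, the package
ships a synthetic-scene generator (kinematic-chain ground truth with
constant bone lengths, depth-like jitter with lower-limb spikes, RGB-like
noise growing as the scene darkens) and all end-to-end properties are
demonstrated on it.

## Worked example

```r
library(lightfuse)
spec <- scene_spec(seed = 1)                 # default synthetic scene, 5-gain sweep
res  <- run_pipeline(run_config(scene = spec))
print(res$calibration)
print(res)
```

```
<light_calibration> a_est = 18.3184, b_est = 4.5205 over 5 conditions
 gain       xbar    h_best    objective
 1.00 0.31327951 0.8418900 0.0000485503
 0.80 0.25062360 0.4491660 0.0001796612
 0.60 0.18796770 0.2415132 0.0002468962
 0.45 0.14097578 0.1627842 0.0002709720
 0.30 0.09398385 0.1137038 0.0002875766
<pipeline_result>
  sigmoid model: a_est = 18.318, b_est = 4.521
  fused  MSE 2.102e-04 | R^2 0.9999 | cos 1.0000 | diff% 0.27 | acc@6 99.0% | acc@8 99.5%
  smooth MSE 7.557e-04 | R^2 0.9998 | cos 0.9999 | diff% 0.67 | acc@6 93.6% | acc@8 95.9%
  rgb    MSE 1.142e-03 | R^2 0.9997 | cos 0.9999 | diff% 0.63 | acc@6 67.1% | acc@8 80.0%
  depth  MSE 3.247e-04 | R^2 0.9999 | cos 1.0000 | diff% 0.33 | acc@6 98.1% | acc@8 99.3%
```

Reading this: the optimal weight `h_best` rises with the gain — bright
scenes shift the blend toward the RGB stream (`a_est > 0`) — and the
adaptively fused stream's pooled joint accuracy at the 8 px threshold
(99.5%) is at or above both single sources across the sweep (RGB 80.0%,
depth 99.3%). The `smooth` row shows the same stream after Kalman
filtering with the fixed covariances; see the vignette for why smoothing
helps on heavily jittered input but costs accuracy on this low-noise
world.

A thin CLI over the same functions lives at `inst/cli/lightfuse.R`
(subcommands `simulate`, `relight`, `calibrate`, `fuse`, `smooth`,
`evaluate`, `run`; exit codes 0/2/3).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating the default synthetic scene, aligning, calibrating
the sigmoid weight model over the gain sweep, fusing, smoothing and
evaluating — and writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/light-adaptive-fusion.Rmd`) describes the
model and its assumptions, what the synthetic generator does and does not
emulate, the numerical choices, and known limitations.
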