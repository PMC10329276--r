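# kneemri

Tools for studying how edge-guided image enhancement and level-set
segmentation support the evaluation of knee MRI in proximal tibia fracture
surgery, and for analyzing the clinical outcome of two surgical approaches
(a small-incision approach versus the common open approach).

Patient images and per-patient clinical tables from such studies are rarely
deposited, so the package is built around *synthetic ground truth*: a
phantom generator that renders tibia-like bone geometry with a known binary
mask and degrades it with blur, downsampling and noise, and a cohort
generator that simulates two surgical arms with prescribed summary
statistics. Every downstream stage — segmentation, reconstruction, image
quality scoring, outcome statistics — is therefore testable end to end.

## What it computes

**Distance-regularized level-set evolution (DRLSE).** A contour is the zero
crossing of a scalar field φ (negative inside), evolved to minimize

    E(φ) = ν R(φ) + γ L(φ) + μ A(φ)

where `R(φ) = Σ P(|∇φ|)` penalizes deviation of `|∇φ|` from a
signed-distance profile through the double-well potential
`P(a) = (1 − cos 2πa)/(2π)² (a ≤ 1)`, `(a − 1)²/2 (a ≥ 1)`;
`L(φ) = Σ β δ_ε(φ)|∇φ|` is the edge-weighted contour length;
`A(φ) = Σ β H_ε(−φ)` is the edge-weighted interior area (balloon term); and
`β = 1/(1 + |∇(G_σ ∗ I)|²)` is the edge indicator of the image. The
gradient flow is integrated by explicit Euler with a smoothed Dirac/
Heaviside pair of width ε.

**Image quality metrics.** `PSNR = 10 log10((2^m − 1)²/MSE)` in dB and the
structural similarity index
`SSIM = (2μ_x μ_y + C1)(2σ_xy + C2) / ((μ_x² + μ_y² + C1)(σ_x² + σ_y² + C2))`
(global by default, sliding-window mode available).

**Reconstruction pipeline.** Degraded phantoms are interpolated back to the
reference grid and refined by edge-gated sharpening
(`image ← image − λ(1 − β)∇²image`), then scored before/after against the
reference with PSNR and SSIM over a seeded multi-phantom suite.

**Clinical outcomes.** BMI (`weight/height²`), the Kolment four-level
knee-function grade from range of motion and pain frequency, the excellent
rate `100·(excellent + good)/total`, pooled two-sample t tests from summary
statistics, Pearson chi-square tests, and a two-arm comparison table
reproducing the structure of the study's outcome tables.

## Worked example

```r
library(kneemri)

spec <- phantom_spec(
  height = 128, width = 128,
  condyles = list(list(center = c(63.5, 63.5), radii = c(20, 20))),
  blur_sigma = 1, factor = 2L, noise_sd = 5, seed = 7L)
ref <- make_phantom(spec)              # reference image + ground-truth mask
deg <- degrade(ref$image, spec)        # blur -> downsample x2 -> noise
rec <- reconstruct(deg, recon_config(segment_pass = FALSE))
rbind(score_pair(upsample(deg, 2L), ref$image, pair_id = "before"),
      score_pair(rec, ref$image, pair_id = "after"))
#>   pair_id   mse psnr_db   ssim
#> 1  before 64.58   30.03 0.9796
#> 2   after 63.61   30.10 0.9801
```

Reconstruction recovers a fraction of the blur loss at the bone edge: PSNR
rises from 30.03 to 30.10 dB and SSIM from 0.9796 to 0.9801 against the
clean reference (on the full default 20-phantom suite PSNR improves for
every phantom).

```r
seg <- segment(ref$image, drlse_params(max_iter = 1200L),
               box_mask(c(128, 128), 25, 25, 102, 102))
dice(seg$mask, ref$mask)
#> [1] 0.984
```

The level-set front, started from a box enclosing the bone, shrinks under
the balloon force until the edge indicator parks it on the bone boundary:
Dice overlap 0.984 against the ground-truth disk.

```r
res <- compare_groups(make_cohort(cohort_spec(seed = 1)))
res$comparison[3:4, c("variable", "small_incision", "common", "p_value")]
#>                variable small_incision         common  p_value
#> 3  operation time (min)  84.87 ± 12.61 129.70 ± 12.18 8.85e-14
#> 4       blood loss (mL) 230.04 ± 34.86 272.08 ± 42.02 1.35e-03

excellent_rate(grade_counts(11, 8, 3, 0, "6m", "small_incision"))
#> [1] 86.36364
```

A simulated 22-versus-18-patient cohort reproduces the published effect
directions (shorter operations, less blood loss in the small-incision arm,
both significant), and the excellent rate computed from the published
6-month grade counts of the small-incision arm is 86.36%.

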