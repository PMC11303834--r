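# myomap

Quantitative analysis of high-resolution 3-D cardiac image volumes:
myocyte-aggregate orientation mapping, helical-angle profiling, layered
wall morphometry, mitral-annular-disjunction quantification,
contrast-to-noise assessment, and Holm–Šidák-corrected group
comparisons — with synthetic phantoms carrying exact ground truth so
every stage is validated by parameter recovery.

## The problem

Modern phase-contrast tomography images whole ex vivo hearts at ~20 µm
isotropic voxels, resolving the laminar texture of myocyte aggregates.
Turning such volumes into numbers a cardiologist can use requires a
chain of image analyses that this package implements as tested,
reusable R functions:

* **Fiber orientation.** Intensity changes little along a myocyte's
  long axis, so the direction of least intensity change marks the fiber.
  With Gaussian-derivative gradients at scale σ_g, the structure tensor
  `T = G_{σ_s} ∗ (∇I ∇Iᵀ)` is eigendecomposed per voxel
  (λ1 ≥ λ2 ≥ λ3) and the eigenvector **e₃** of the smallest eigenvalue
  is the fiber direction (sign-ambiguous; all consumers are
  sign-invariant).
* **Helical angle.** In a cylindrical frame (r̂, ĉ, ẑ) centered on the
  left-ventricular long axis, `α_h = atan2(e₃·ẑ, e₃·ĉ)` folded into
  [−90°, 90°] — the angle between the fiber's tangential-plane
  projection and the transverse plane. Healthy ventricular walls show a
  smooth transmural transition (≈ +60° endocardium → −60° epicardium).
* **Morphometry.** Sublayer thickness (endocardium/myocardium/
  epicardium) by normal-ray chords at evenly distributed mid-surface
  locations; mitral annular disjunction as the hinge-to-crest axial
  displacement in 5° steps around the annulus; CNR as
  `|μ_tissue − μ_background| / σ_background`.
* **Statistics.** Unpaired t tests across condition (control vs
  diseased) and side (left vs right), step-down Holm–Šidák adjustment
  `p′_(i) = 1 − (1 − p_(i))^(m−i+1)` within one family per sublayer,
  α = 0.05.

Real whole-heart volumes are not desk-scale obtainable, so the package
generates annular LV phantoms whose laminar texture follows a prescribed
helix law `α(d) = α_endo + (α_epi − α_endo)·d` with per-voxel ground
truth, plus layered slab and hinge/crest landmark phantoms. See the
methods vignette (`vignettes/myomap-methods.Rmd`) for the full model
description and design rationale.

## Worked example

Generate a noisy LV phantom (64³ voxels, 20 µm, +60° → −60° helix law,
SNR 10), recover the orientation field, and profile the helix angle:

```r
library(myomap)

spec <- lv_phantom_spec(shape = c(64, 64, 64), voxel_size_um = 20,
                        inner_radius_um = 300, outer_radius_um = 540,
                        noise_sd = 5, seed = 42)
ph <- generate_lv_phantom(spec)

orient <- estimate_orientation(ph$volume)
cl     <- estimate_centerline(ph$labels, label = 1)   # lumen centroids
hm     <- compute_helix_angle_map(orient, cl, mask = ph$labels == 2L)
hm
#> <helix_map> 64 x 64 x 64 voxels, 52546 valid (20.0%)
#>   angle range [-64.4, 69.6] deg, median 4.3 deg

err <- abs(unclass(hm) - ph$truth$alpha_deg)
median(err[!is.nan(err)])
#> [1] 5.69                           # degrees, on this thin 12-voxel wall

depth <- transmural_depth(ph$labels == 2L, ph$labels == 1L, ph$labels == 0L)
transmural_profile(hm, depth, n_bins = 5)
#>   depth_mid mean_deg median_deg sd_deg     n
#> 1       0.1    41.42      41.19   8.88  8331
#> 2       0.3    20.78      20.64   9.68 13798
#> 3       0.5    -1.16      -1.19  10.10 15432
#> 4       0.7   -23.20     -23.45   9.42 12247
#> 5       0.9   -40.60     -39.63   7.88  2738
```

The profile reproduces the prescribed endo-to-epi transition: bin means
fall monotonically from +41° to −41° (bin centers at depths 0.1–0.9
correspond to prescribed angles +48° to −48°; the remaining compression
comes from tensor smoothing over the steep transmural gradient of this
deliberately thin demonstration wall — the 128³ headline geometry
recovers the law to ≈ 2.8° median error). `plot(hm)` renders the
mid-slice color map.

Thickness, disjunction, CNR and statistics follow the same pattern; the
self-contained demo pipeline runs the orientation chain end to end and
writes CSV/JSON outputs plus a checksummed manifest:

```r
run_pipeline(pipeline_config("demo_out", stages = "demo", seed = 1))
```

A thin CLI wraps the same stages:

```sh
Rscript inst/cli/myomap demo --out demo_out --seed 1
```

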