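---
title: "Myocyte orientation mapping and cardiac morphometry: methods"
author: "myomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myocyte orientation mapping and cardiac morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

High-resolution 3-D scans of whole ex vivo hearts resolve the myocardium
down to the scale of myocyte aggregates. `myomap` implements the
quantitative analyses such data support:

1. **Per-voxel fiber orientation** by the structure-tensor method.
2. **Helical angle maps** of the ventricular wall in a cylindrical frame
   centered on the left-ventricular long axis, with binned transmural
   profiles.
3. **Layered wall-thickness morphometry** (endocardium / myocardium /
   epicardium) by normal-ray measurement on a label map.
4. **Mitral-annular-disjunction (MAD) profiles**: hinge-to-crest
   displacement in 5° steps around the annulus.
5. **Contrast-to-noise ratios** of tissue ROIs against a background ROI.
6. **Group comparison** of morphometric measurements by unpaired t tests
   with step-down Holm–Šidák correction at α = 0.05.

Because whole-heart scan volumes are far beyond desk scale, the package
also ships **synthetic phantoms with exact ground truth** — an annular
LV wall with a prescribed transmural helix-angle law, layered wall
slabs, and hinge/crest landmark curves — so every stage is validated by
parameter recovery rather than by comparison to an unavailable dataset.

## Conventions

Volumes are arrays indexed `[iz, iy, ix]` with isotropic voxels of size
`voxel_size_um` micrometres. R indices are 1-based; the voxel
`[iz, iy, ix]` is centred at world coordinate
`((ix-1), (iy-1), (iz-1)) * voxel_size_um`. World points and vectors are
`(x, y, z)` triples in µm, right-handed.

## The structure tensor and the fiber direction

Cardiomyocytes form elongated aggregates whose image intensity changes
little along the cell's long axis and strongly across it. The structure
tensor formalizes this: with `∇I` the intensity gradient computed by
Gaussian derivatives at scale `σ_g`, the tensor at a voxel is

    T = G_{σ_s} * (∇I ∇Iᵀ),

the outer product smoothed componentwise with a Gaussian of scale
`σ_s`. `T` is symmetric positive semidefinite; sorting its eigenvalues
`λ1 ≥ λ2 ≥ λ3`, the eigenvector `e3` of the **smallest** eigenvalue
points along the direction of least intensity change — taken as the
fiber direction. `e3` is defined only up to sign; it is stored with its
largest-magnitude component positive and every consumer in the package
is sign-invariant.

Parameters (`orientation_config()`):

* `sigma_g` (voxels, default 1.0) — derivative scale. Small enough to
  resolve laminar textures of wavelength ≥ 4 voxels.
* `sigma_s` (voxels, default 2.5) — tensor integration scale. It must
  exceed `σ_g`, otherwise the tensor is rank-1 at every voxel and the
  fiber direction is undefined. The default suits textures of
  wavelength 4–12 voxels.
* `eps_lambda` (relative, default 0.05) — a voxel is flagged invalid
  when `(λ2 − λ3)/λ1 < eps_lambda`; there is then no unique direction of
  least change (isotropic or planar-degenerate neighborhood).

Numerical choices: all filtering is separable with mirror-reflect
boundaries; voxels within `ceiling(3·max(σ_s, σ_g))` of the volume
border are flagged invalid because the filter support is incomplete
there; exact eigen-ties are resolved by flagging, never by guessing;
eigendecomposition is done per voxel in compiled code and is checked in
the tests against R's dense `eigen()` voxel by voxel. A constant volume
yields zero tensors plus a warning flag rather than an error.

## The cylindrical frame and the helical angle

The left-ventricular centerline is the origin of the cylindrical system.
`estimate_centerline()` computes per-slice centroids of a cavity (or
annulus) mask and fits a least-squares straight line through them. Two
robustness rules matter in practice: empty slices are skipped, and
slices whose mask area falls below 90 % of the median slice area are
excluded — for a tilted chamber the end slices cut the cavity only
partially and their centroids are biased off-axis. A user-supplied
centerline (point + direction) can be used instead. We deliberately fit
a straight axis rather than a curved spline: only the long-axis
direction is needed to define the transverse plane, and a curved-axis
variant would change the frame only near the apex. The transverse plane
is the plane normal to the *fitted axis*, not the image z-plane, which
matters for tilted hearts.

At a voxel at perpendicular distance ρ from the axis the local
orthonormal triad is `ẑ` (axis direction), `r̂` (unit vector from axis to
voxel), and `ĉ = ẑ × r̂`, so that `r̂ × ĉ = ẑ`. Voxels within one voxel of
the axis have no defined frame.

The **helical angle** of a fiber `e3` is the angle of its projection
onto the tangential plane span(`ĉ`, `ẑ`) measured from the transverse
plane:

    α_h = atan2(e3·ẑ, e3·ĉ)  folded into [−90°, 90°].

The folding (flip `e3` so its circumferential component is
non-negative) makes the map invariant under `e3 → −e3`. The sign
convention: `α_h > 0` when the fiber climbs along `+ẑ` while advancing
along `+ĉ` — a right-handed helix; reversing the centerline direction
flips the sign, so the base-to-apex orientation of the axis is the
user's choice. Voxels whose tangential projection norm is below 0.2 are
flagged invalid: near-radial fibers have no meaningful helical angle,
and small projections amplify angular noise.

Transmural position is quantified by the normalized depth
`d = D_endo / (D_endo + D_epi)` with `D` exact Euclidean distances to
the endocardial-side and epicardial-side compartments. This two-distance
form is well defined for curved walls and reduces to linear depth in a
slab. `transmural_profile()` bins `α_h` by `d` (10 equal bins by
default) and reports mean, median, sd and count per bin.

## The LV phantom and what it emulates

`generate_lv_phantom()` builds a cylindrical-annulus wall whose fiber
field follows the linear transmural law
`α(d) = α_endo + (α_epi − α_endo)·d` (defaults +60° → −60°, the
textbook left-ventricular transition), with exact per-voxel ground
truth (unit fiber vectors, wall mask, depth).

The texture must satisfy the estimator's physical premise — intensity
constant along the local fiber — *by construction*, so that recovery
error measures the estimator, not the phantom. Two sinusoidal laminar
systems are summed:

* **Radial laminae** `cos(2πρ/λ)`: gradient exactly radial, hence
  exactly orthogonal to the (tangential) fiber everywhere.
* **Helical laminae** with phase `−sin(α)·ρ_s·θ + cos(α)·z`, frozen over
  radial shells of width `shell_width_voxels` (default 2) with an
  independent random phase per shell. Within a shell the in-plane
  gradient is `−sin(α)(ρ_s/ρ)ĉ + cos(α)ẑ` — orthogonal to the shell's
  fiber direction — and the phase jumps between shells lie on ρ = const
  surfaces, adding only radial gradient energy, which is orthogonal to
  the fiber too.

Why shells? The continuous-α closed-form phase is exactly
fiber-orthogonal but contains secular terms growing with θ and z whose
radial frequency aliases on the grid. Freezing the phase per shell
bounds the gradient at the cost of quantizing the helix law by
`α′ · shell_width / 2` across the wall. Width 2 balances radial phase
coherence against this quantization under the default smoothing scales;
with it, the noise-free median recovery error at the default geometry
(wall radii 30–55 voxels, 120° transmural sweep) is ≈ 2.3°, within the
3° design bound, and ≈ 2.8° at SNR 10.

The helical phase is discontinuous across one azimuthal half-plane (the
branch cut of θ); that thin sheet of voxels carries a corrupted texture,
which the median-based recovery metrics tolerate.

The phantom emulates the geometry and texture premise of real
high-resolution cardiac volumes, **not** their full physics: there is no
phase-contrast fringe structure, beam hardening, ring artifact,
trabeculation, vasculature, or multi-chamber anatomy, and the wall is a
perfect annulus. Recovery results therefore demonstrate estimator
correctness under the stated model, not segmentation robustness on real
scans. The signal-to-noise ratio of the real scans is not published per
voxel size, so noise is a swept parameter: `add_noise()` controls the
amplitude-to-noise ratio explicitly, and the headline experiments use
SNR 10 (texture amplitude 50, Gaussian noise sd 5).

## Wall thickness

`measure_layer_thickness()` mimics caliper-style measurement: at
`n_locations` (default 15) points spread evenly over the wall
mid-surface, a ray is cast along the local wall normal and each
sublayer's chord length is reported in µm. Mechanics:

* Distances to the endocardial-side and epicardial-side exteriors
  (identified by 6-neighborhood adjacency to the inner/outer sublayer)
  give the mid-surface (`|D_in − D_out| ≤ 1` voxel) and, via the
  gradient of their smoothed difference, the outward normal.
* "Evenly distributed" means equally spaced positions along the first
  principal component of the **measurable** mid-surface — points whose
  full-thickness ray stays inside the volume (clearance test from the
  distance fields). Ties at a target position are broken by the seed,
  making placement reproducible.
* Layer boundaries along the ray are located by coarse scan plus
  bisection to ≈ 1e−9 voxels, so an axis-aligned slab with
  whole-voxel layers (e.g. 200/2000/400 µm at 20 µm) is recovered
  exactly; oblique walls are recovered within one voxel.
* A ray that leaves the volume before clearing the wall skips that
  location with a warning; fewer usable locations than requested is an
  error, as is a label map with no wall.

Normal-ray chords (rather than sphere-fitting local thickness) mirror
manual measurement practice; per location the sublayer chords sum to
the total wall chord by construction.

## Mitral annular disjunction

`compute_mad_profile()` parameterizes the hinge and crest landmark
curves by their angle about the annular axis (unwrapped, origin at the
first hinge point by default), linearly interpolates both at a common
5° grid over the overlapping arc, and reports the displacement at each
node. The default measure is **axial** — the separation along the
annular axis — with 3-D Euclidean distance as an option
(`mode = "euclidean"`); for a hinge displaced parallel to the axis the
two coincide. Angular gaps larger than the analysis step refuse to
interpolate, and non-overlapping arcs are an error. Phantom curves are
generated at 1° resolution, so the 5° analysis grid is always a
sub-sampling.

## Contrast-to-noise ratio

For each replicate ROI, `CNR = |mean(tissue) − mean(background)| /
sd(background)` with the embedding-agar region as background. This is
the common single-background definition; it is invariant under global
affine intensity maps with positive gain (both numerator and
denominator scale by the gain) and degenerates only when the background
has zero variance, which is an error. The conventional report is five
replicate ROIs per tissue (aorta, LV wall, epicardial fat) with a
mean ± sd summary per tissue.

## Statistics

Sublayer thicknesses are compared across two-level groupings (control
vs diseased condition; left vs right side) with unpaired two-sample
t tests — pooled-variance by default, Welch optional — and the
**step-down Holm–Šidák** adjustment applied within one family per
sublayer:

    sort p ascending;  p′_(i) = 1 − (1 − p_(i))^(m − i + 1);
    enforce monotonicity by running maximum;  map back to input order.

`stats::p.adjust` offers Holm–Bonferroni and single-step Šidák but not
this step-down Šidák form, so it is implemented directly and tested
against an independent closed-form evaluation to 1e−12 as well as by
simulation: under a simulated global null (1000 replicates, 15
measurements per group) the family-wise error rate stays within two
binomial standard errors of the nominal 0.05, and a 3-sd mean shift at
n = 15 is detected in > 99 % of replicates. The family definition (per
sublayer, across the stated contrasts) follows how per-layer
significance is conventionally reported; a single global family would
be more conservative and can be obtained by calling
`holm_sidak_adjust()` on the pooled p-values.

Floating-point detail: at the last step-down rank `1 − (1 − p)` can
round below `p`, so the implementation clamps `p′ ≥ p` to keep the
adjusted-not-smaller-than-raw invariant exact.

## Pipeline, formats, reproducibility

`run_pipeline()` executes the configured stages (self-contained `demo`,
or `helix` / `thickness` / `mad` / `cnr` / `stats` on user files),
validates every referenced input path *before* any computation, writes
all exports into the output directory, and emits a JSON manifest with
MD5 checksums. All randomness (noise, location placement, simulation
replicates) flows from the single configured seed, and repeated runs are
byte-identical. A thin command-line wrapper (`inst/cli/myomap`, exit
codes 0/1/2 for success/usage/runtime) exposes the same stages.

Formats: NIfTI-1 is the canonical volume format (32-bit-float round
trips are bitwise lossless; the voxel size is stored in µm units in the
header). Multi-page TIFF is supported with one caveat: the underlying
TIFF library stores float samples faithfully only in [0, 1], so volumes
are rescaled on write and the affine map plus voxel size recorded in a
JSON sidecar that the reader applies transparently. Label maps are
8-bit; curves and all tabular outputs are CSV. Anisotropic voxel headers
are rejected unless an explicit isotropic override is given — nothing is
resampled silently.

## Problem sizes

The test suite exercises 48³–64³ phantoms for unit-level recovery
(seconds each) and one 128³ phantom — the headline geometry with
30/55-voxel wall radii at 20 µm — in the end-to-end recovery checks.
The acceptance script re-runs the 128³ recovery, the slab and MAD
recoveries, the 1000-replicate null simulation, and the demo-pipeline
determinism check from scratch; the whole script completes in well
under a minute on one CPU. These sizes were chosen so the full
validation cycle runs interactively while keeping the headline phantom
at the wall-geometry proportions of a real left ventricle at 20 µm.

## Known limitations

* The straight-axis cylindrical frame is inaccurate near the apex of a
  real heart; a curved-centerline frame is a possible extension.
* Structure-tensor smoothing across a curved wall biases the helical
  angle slightly toward ±90° at small radii (≈ 1.4° at the default
  geometry, larger for thin, tightly curved walls); the effect shrinks
  with wall radius.
* The CNR formula is the standard single-background definition; reports
  produced with other CNR conventions are not directly comparable.
* Thickness measurement assumes the three sublayers form one contiguous
  wall with exterior on both sides; it does not segment layers itself.
* Only the primary fiber direction is computed — no sheetlet
  (secondary/tertiary eigenvector) analysis and no tractography.
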