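---
title: "Temporal translation in a 4D developmental atlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal translation in a 4D developmental atlas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devatlas)
```

## The problem

A developmental brain atlas anchors population-averaged templates at a few
postnatal ages — here P4, P7, P14, P21, P28 and P56 — and links temporal
neighbours by nonrigid registration. `devatlas` implements everything
downstream of those registrations: the displacement-field algebra, the
synthesis of models for every intermediate day, translation of volumes and
coordinates between arbitrary ages, landmark-based accuracy statistics, and
reconstruction of 3D expression volumes from sparse registered sections.
Registration itself (elastix-style translation/affine/B-spline pipelines) is
deliberately out of scope: fields enter the package as data, or are
generated analytically by the synthetic-fixtures module.

## Conventions and the field model

Coordinates are 0-based continuous voxel indices in the order
anterior–posterior, superior–inferior, left–right; conversions to physical
micrometres happen only at the statistics and I/O boundaries. All spaces in
one chain share grid shape and spacing (the templates are
dimension-standardized before registration), which is what allows
displacements to be stored in voxel units and makes temporal scaling of a
field on the shared grid well-defined.

A field is a *pull* field `U` indexed on its target grid: volume resampling
reads the source at `x + U(x)`; the same map carries points from target
space to source space. The stored pairwise fields are the *backward*
transforms (target = younger anchor, source = older); everything else is
derived:

* **Inversion** (backward → forward) uses the fixed-point iteration
  `V_{k+1}(x) = −U(x + V_k(x))` with `V_0 = −U`. Defaults: tolerance 0.05
  voxel (1 µm at 20 µm spacing — well below the resolution of any landmark
  statistic) and at most 50 iterations. The returned field carries the
  composition residual `max |U(x + V(x)) + V(x)|` as a quality attribute;
  real registration fields are never exactly invertible at brain
  boundaries, so a residual above ten times the tolerance attaches a
  warning flag rather than failing.
* **Composition** of an inner step `W` and an outer step `U` is
  `K(x) = W(x) + U(x + W(x))`, with `U` interpolated trilinearly.
* **Temporal scaling** multiplies a field by a fraction `f ∈ [0, 1]`. This
  linear rule is the package's explicit first-order stand-in for geodesic
  (stationary-velocity) interpolation of a deformation: it is exact for
  translations and for the affine part of a warp, and consistent with
  weighting temporal neighbours linearly by age distance. Diffeomorphic
  interpolation is a documented non-goal.

Off-grid field values are interpolated trilinearly with edge clamping (no
extrapolation — bounded and deterministic). Volume samples falling outside
the source domain are filled with 0, matching zero-padded backgrounds.
Nearest-neighbour sampling (mandatory for label volumes, so that no label id
can be invented) rounds coordinates exactly at `.5` toward the smaller
index, a deterministic tie rule.

## Intermediate-age models and routing

For a target age `t` bracketed by anchors `y < t < o`, the fraction is
`f = (t − y)/(o − y)` and the weights are `w_y = 1 − f`, `w_o = f`:

```{r}
plan_interpolation(8, zero_ch <- make_synthetic_chain(
  ages = c(4, 7, 14, 21, 28, 56), shape = c(12, 10, 10),
  velocity = c(0, 0, 0)))
```

The model volume warps the younger template by the forward field scaled to
`f` and the older by the backward field scaled to `1 − f`, both landing on
the intermediate grid, and averages them with `w_y`, `w_o`. Only the two
bracketing anchors ever contribute, and an anchor-age request returns the
stored template bit-identically. Enumerating all integer ages P4–P56 yields
47 interpolated models plus 6 templates = 53 volumes, split for practical
file sizes into P4–P20, P21–P37 and P38–P56:

```{r}
series <- compile_4d(zero_ch, split = list(c(4, 20), c(21, 37), c(38, 56)))
table(series$manifest$kind)
```

Arbitrary age-to-age routes chain full backward (or forward) fields through
the intervening anchors, plus at most one temporally scaled terminal step
per non-anchor endpoint. One routing choice was genuinely open: how to leave
a *non-anchor* age. The package scales the stored pair field and
reinterprets its endpoints (leaving `t` toward the younger anchor uses
`f · B`; toward the older, `(1 − f) · F`), rather than inverting the scaled
entry field; the two agree exactly for translations and to first order
otherwise, and reusing the stored fields keeps routes cheap and cacheable.
Forward fields are inverted once per pair and cached; composed route fields
are cached by (source, target). Segmentations are only ever carried *down*
from the adult anchor with nearest-neighbour sampling — requests upward in
age are refused, since only the backward transform is defined for them.

## Landmark validation statistics

Each rater is scored, landmark by landmark, by the Euclidean distance (µm)
to the median of the *other* raters' coordinates; the transform under test
is scored against every subset of `R − 1` raters and the subset distances
averaged, so that both subjects face references built from the same number
of annotators. Landmarks not identified by every rater at an age are
excluded from that age entirely. Two points the source procedure leaves
open are settled here and exposed:

* **"Median coordinate" is componentwise** (per-axis). It is the convention
  that yields a well-defined coordinate for any rater count; the geometric
  (spatial) median is a possible alternative but has no closed form for
  even counts. The median is used at all because it is robust: one wild
  annotation moves the median of three by a bounded amount.
* **The t test is paired** over landmarks by default — both subjects are
  scored on the same landmark set, so pairing is statistically the natural
  reading — with an unpaired Welch variant behind `paired = FALSE`.
  Zero-variance differences report `t = 0`, `p = 1` with a degeneracy flag
  instead of erroring.

Error heatmaps assign every voxel the error of its nearest assessed
landmark (ties toward the smaller landmark id), and per-region summaries
look labels up at the rounded landmark voxel.

## Preprocessing operators

The template-conditioning chain: block-mean downsampling (block-mode for
labels, ties toward the smaller id), posterior zero-padding along the AP
axis (45 voxels is the standard value for matching the adult reference's
rostrocaudal extent at 20 µm), separable linear resampling from anisotropic
20×20×50 µm stacks to isotropic 20 µm, integer-voxel origin alignment, 3D
CLAHE, and multiplicative matching of foreground means (foreground =
strictly positive voxels, since backgrounds are zero-padded). Two
conventions worth noting:

* `resample_to_isotropic` samples at voxel centres and extends *linearly*
  (not by clamping) from the two nearest samples beyond the ends, so affine
  signals are reproduced exactly over the whole output extent. The output
  extent is `round(physical extent / output spacing)` per axis.
* `clahe3d` quantizes to 256 bins, clips each tile histogram at
  `clip_limit` (default 3) times the uniform bin height, redistributes the
  excess uniformly, and blends the per-tile equalization mappings
  trilinearly between tile centres (default 4×4×4 tiles). The reference
  procedure's exact CLAHE parameters are unstated, so these defaults are
  this package's own and are plain function arguments. Tilt removal is
  *not* an operator: it was a manual step in the source workflow, and the
  package accepts already-detilted inputs.

## Sparse-section reconstruction and quantification

Registered 2D sections are rasterized into the atlas grid (plane or affine
pixel-to-voxel anchoring; collisions average), then gaps are filled by
K-nearest-neighbour interpolation with inverse-distance weights `1/d` over
unrestricted 3D neighbours. `k` and the weight exponent are unstated in the
source procedure; the defaults are `k = 4` and exponent 1, both exposed.
Exact coincidences (`d = 0`) take the known value directly; known voxels
are never modified, making the fill idempotent and bounded by the known
value range. Region loads are plain area fractions
`positive pixels / region pixels` per label, with an explicit exclusion
list (typically fibre tracts and ventricular system) supplied as ids, not
hard-coded names. Expression time series reuse the template machinery: the
two bracketing data-age volumes are translated into the requested age and
averaged with the same linear temporal weights.

## The synthetic fixtures, and what they do not show

Phantoms are smooth ellipsoidal bumps `(1 − ρ²)²` with nested label shells
whose semi-axes grow affinely with age (`0.45 + 0.006 · age` of the
half-extent by default — chosen only to be monotone and to keep the P56
phantom inside the grid; no biological realism is claimed). Analytic warp
families — translations, centred scalings, gradient-bounded sinusoids —
carry closed-form inverses, so inversion, composition, routing and
interpolation can be checked against exact answers. Simulated raters are
truth plus isotropic Gaussian noise, the simplest exchangeable model of
independent annotators.

Passing these tests shows the *machinery* is correct: the algebra matches
closed forms, weights and routes are exact, statistics equal brute-force
enumeration. It does not show that real inter-age registrations are
accurate — real templates have texture, asymmetric growth, acquisition
differences between age groups, and registration error, none of which the
phantoms emulate. Accuracy on real data is a property of the supplied
deformation fields, which is exactly what the landmark statistics are for.

## Problem sizes and budgets

The test suite and the acceptance script run field-algebra oracles on 64³
grids, interpolation-recovery checks on ~44×36×36 translation chains,
KNN-reconstruction oracles on 12³ grids, and 200-replicate noise-monotonicity
sweeps — sizes chosen so the full suite completes in well under a minute on
one CPU while keeping every tolerance meaningful (inversion checks at 0.05
voxel, composition at 1e−4, volume round trips at 2% of dynamic range,
centroid recovery at 0.25 voxel).

## Known limitations

* Linear field scaling, not geodesic interpolation: fractional transforms
  of strongly nonlinear warps are first-order approximations.
* Inversion assumes diffeomorphic-scale fields; global invertibility is
  not verified (the residual attribute is the honest signal).
* The KNN infill is a brute-force chunked search — fine at atlas-map test
  scales, not tuned for full-resolution whole-brain grids.
* No anisotropic runtime grids: anisotropy is handled only by the
  preprocessing resampler. No surface meshes, no bias-field correction, no
  registration estimation.
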