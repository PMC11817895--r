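---
title: "Border-gradient metrics for stereotactic plan quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Border-gradient metrics for stereotactic plan quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `sbgrad` defines, computes and validates its
metrics, and why the genuinely open design choices were resolved the way
they were.

## The quantities and their assumptions

All metrics operate on a 3D absorbed-dose field sampled at voxel centers on
a regular mm grid, a set of binary structure masks on the same grid, and a
prescription (Rx, Gy) with a fraction count. Doses are physical dose only;
no biologically effective dose or EQD2 conversion is applied, so
cross-fractionation comparisons rely on the fractionation-specific goal
tables rather than dose conversion.

**Isodose surfaces.** An "isodose line" at level x%Rx is interpreted as the
full 3D level surface of the dose field, not a planar contour. Surface
points are located sub-voxel: along every grid edge whose endpoint doses
straddle the level, the crossing is placed by linear interpolation, which is
exact for the trilinear interpolant the grid defines. This matters because
clinically interesting gradients (10%Rx within ~0.5 mm for hot-core
radiosurgery plans) live below typical grid spacings.

**SBG.** The steepest border gradient at level x is
`(100 − x) / d_min(x)` %Rx/mm, with `d_min(x)` the minimum 3D Euclidean
distance between the x%Rx surface and the prescription surface. The minimum
is taken over all connected components by default (`component = "all"`); a
`"nearest"` mode restricts the x% surface to the component nearest the
primary target for cases with detached low-dose islands. The default is
global because a single shortest distance per level is the conservative
reading and the localized variant is available when the gradient near one
specific organ is the question.

**VG, conformity, homogeneity.** `VG(x) = VOL(x%Rx)/TV` includes all
connected components of the level region. `VG(100)` equals the RTOG
conformity index, and the traditional gradient index is `VG(50)/VG(100)` by
definition in code, not by separate computation, so the identity is exact.
The Paddick index uses the standard form `TV_PIV²/(TV·PIV)`. The
homogeneity index is `(D2 − D98)/D50` from the exact DVH.

## Numerical choices

**Volumes are voxel-center counts.** Structure volume, PIV, VOL(x%) and the
target∩PIV overlap are all `count × voxel volume`. Keeping one counting rule
everywhere makes the conformity identities exact: RTOG CI equals VG(100) to
the last bit, PCI = 1 exactly when the prescription region coincides with
the target, and PCI ≤ 1 always (it is a Cauchy–Schwarz-type bound on
counts). A boundary-fraction-corrected volume (trilinear supersampling of
crossing voxels) is available via `extract_isodose(refine = TRUE)` for
standalone volume estimates, but it is deliberately not the default: mixing
corrected isodose volumes with counted mask volumes breaks those identities
(a corrected PIV on a plateau plan is smaller than the counted TV, pushing
PCI above 1). At the grids used here the counting error is far below the
2–3% at which volume accuracy is assessed.

**Plateau-kink refinement.** When a plan is prescribed at its own plateau
edge, the dose equals Rx throughout the target interior and the Rx level set
degenerates: on a crossing edge the inside node sits exactly at the level,
and naive interpolation puts the surface at the node — up to one voxel
inside the true border, which at 0.5 mm grids is a ~25% error in a 2 mm
border distance. When the inside node is at the level (relative tolerance
1e-9) and the field is flat one node further in, the crossing is instead
relocated by extrapolating the falloff line through the next two outside
nodes, restoring O(h²) accuracy. Fields without plateaus never trigger the
branch.

**Surface distances.** `d_min` is the exact nearest-neighbour distance
between the two sub-voxel vertex clouds, computed in C++ with a uniform
spatial hash whose cell size is set from a cheap upper bound so queries
touch O(1) cells. For smooth nested surfaces this agrees with a continuous
surface-to-surface distance to O(h²) (vertex spacing enters quadratically
through surface curvature), and it is precisely the quantity the all-pairs
brute-force oracle in the test suite measures. A discretised unsigned
distance field was considered and rejected: it adds its own interpolation
error without changing the measured minimum. Truncated surfaces (level
region touching the grid boundary) flag the distance as a lower bound and
the volume as a lower bound rather than erroring.

**DVH conventions.** The cumulative DVH is exact (sorted per-voxel doses,
no bins). Dx interpolates linearly in cumulative volume between adjacent
sorted voxel doses; ties in dose are handled by the cumulative function
itself, so no tie-break rule is needed. D100 is the minimum voxel dose. The
near-maximum dose D0.01cc accumulates sorted-descending voxel volumes to
0.01 cm³ and interpolates within the straddling voxel — a dialect choice;
the whole-voxel alternative ("dose of the voxel in which 0.01 cm³ is
reached") differs by at most one voxel's dose step and a `dmax_mode =
"voxel"` switch in the goal evaluator exposes the single-hottest-voxel
convention. Structures smaller than 0.01 cm³ fall back to the hottest voxel
with a warning.

**Degenerate inputs.** Empty masks, levels outside the dose range, disjoint
resampling grids and non-positive prescriptions are errors with messages
naming the object. Identical paired metric vectors make the signed-rank
test undefined; the comparison reports p = 1 with a `degenerate` flag
instead of failing.

## The synthetic generator: what it emulates, what it does not

The generator builds dose as an analytic, monotone profile of the *signed
distance to the target surface* — not distance to the center — so the
falloff in %Rx/mm is uniform over the whole border and SBG ground truth is
exact by construction. Three profile families emulate the falloff regimes
of the clinical delivery systems:

- `linear(g)`: plateau at Rx inside, `g` %Rx/mm outside (default g = 5, a
  mid-range clinical falloff). The level-x surface is the parallel surface
  at offset `(100 − x)/g`, so for a sphere of radius R,
  `VG(x) = ((R + offset)/R)³`.
- `logistic(prescription_isodose, scale)`: sigmoid of signed distance with
  maximum dose `Rx·100/p`. `p = 50` puts the prescription at the steepest
  point of the profile with a ~2×Rx hot core (radiosurgery normalization;
  scale default 2.4 mm reproduces ~20 %Rx/mm at the 90% level); `p = 90`
  prescribes at the shoulder (arc/proton normalization; scale 1.2 mm gives
  ~11 %Rx/mm there). These two settings reproduce the opposite SBG level
  trends that prescription placement induces: hot-core plans are steepest
  near the 90% level, shoulder plans steepest below it.
- `piecewise(knots)`: monotone linear interpolation for arbitrary measured
  falloffs; its inverse is obtained by 1D root finding and flagged
  `numeric_inverse` in the ground truth.

An optional anisotropy multiplies outside distances in a half-space by a
factor (`Inf` = zero exit dose), emulating a beam-stopping sector such as a
proton distal edge; its expected effect — markedly lower VG at the 20%
level than the matched isotropic plan — has a closed-form value from the
half-space split. Closed-form border distances are only claimed for
isotropic falloff (with a sharper sector the level surfaces pinch near the
sector boundary), so `ground_truth()` reports `d_min`/SBG as `NA` for
anisotropic specs. Hot-core interior quantities (HI, Dx, Dmax) have closed
forms for sphere targets; ellipsoid targets get exact border distances (the
parallel-surface property of convex bodies) and Steiner-formula volumes
with numerically integrated surface area and mean-curvature integral.

Defaults are 24 Gy in 3 fractions (the mid-range of the 21–27 Gy/3 fx
reirradiation regime; the 40–45 Gy/5 fx regime is selected via
`n_fractions`), a 10 mm sphere target, and a 0.5 mm isotropic grid in an
80 mm cube — fine enough to resolve half-millimetre falloff at ~4M voxels.
Optional Gaussian noise is off by default: the metrics are defined on the
noiseless field and noise exists only for robustness experiments.

What the generator does **not** emulate: real beam penumbra shapes,
scatter tails, heterogeneity effects, multi-target interplay, or any
machine-specific deliverability. Passing the synthetic recovery tests shows
the *measurement chain* is correct (surfaces, distances, volumes, DVH
arithmetic), not that any delivery system achieves a given gradient;
profile parameters were chosen to reproduce orderings and realistic
magnitudes, not any specific cohort's numbers.

## Goal auditing and plan comparison

Goal tables are YAML/JSON transcriptions of printed constraint tables, one
entry per row (`structure`, the printed expression such as `"Dmax < 13 Gy"`
or `"V12 Gy < 3 cm3"`, and an optional fraction-count selector). `Dmax` in
tables means D0.01cc, matching the panel's definition of maximum dose.
Percent thresholds on dose metrics are relative to the prescription.
Qualitative "as low as reasonably achievable" rows are represented as
`advisory` entries: their achieved values are reported but they are never
pass/fail. Reports have stable ordering and fixed float formatting, so a
given plan and table produce identical bytes.

Plan comparison uses the paired Wilcoxon signed-rank test (two-sided, the
conventional choice when sidedness is unstated), delegated to
`stats::wilcox.test` with the conventions pinned down: zero differences
discarded, exact distribution for ≤ 25 untied non-zero pairs, normal
approximation with continuity and tie correction otherwise, p = 1 with a
flag for all-zero difference vectors. Raw p-values are reported without
multiple-testing adjustment, with a note in the report footer. The test
suite checks the exact branch against exhaustive sign enumeration for
n ≤ 10.

## Problem sizes and verification

The validation suite measures, among others: SBG recovery on the linear
sphere (5 %Rx/mm at every level within 5% at 0.5 mm spacing, error
decreasing monotonically over 1.0 → 0.5 → 0.25 mm grids on a 46 mm cube);
VG recovery within 3%; the definitional identities to floating tolerance;
DVH metrics against a brute-force sort-and-scan oracle to 1e-9 relative on
100 random 1000-voxel instances; and surface distances against all-pairs
brute force on ≤ 5000-vertex surfaces. These sizes were chosen as the
smallest that exercise sub-voxel behaviour convincingly while keeping the
whole suite in the low minutes on a single CPU.

## Known limitations

- DICOM support covers uncompressed little-endian transfer syntaxes with
  identity in-plane orientation — the common case for exported RT dose
  grids; rotated or compressed objects are rejected with a message.
- Masks are binary: partial-volume structure occupancy is not modeled, so
  very small structures (a few voxels) carry counting noise in all
  volume-based metrics; D0.01cc on structures near 0.01 cm³ falls back to
  the hottest voxel.
- SBG convergence with grid spacing is characterized empirically on the
  synthetic plans; export grids of clinical planning systems vary and
  coarse grids (≥ 2 mm) visibly underestimate steep gradients.
- `VG` at levels whose region leaves the grid is a lower bound (flagged),
  not an error; interpreting flagged values is the caller's responsibility.
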