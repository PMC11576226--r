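---
title: "Functional connectivity density mapping and molecular coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping and molecular coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdcoupling)
```

This vignette is the package's own account of the methods it implements:
the graph model behind voxel-wise functional connectivity density (FCD),
the SUVR normalization of molecular PET images, the rank-based two-step
corrected inference, the synthetic-study generator the tests run on, and
the numerical and design choices that were genuinely open.

## The FCD graph model

All connectivity is pairwise temporal Pearson correlation `C_ij` between
voxel BOLD time series on one common grid. Two graphs are built over the
masked voxels with a strict, one-sided edge rule `C_ij > T_c`
(`T_c = 0.6` by default; negative correlations never form edges):

* **Global FCD.** `gFCD(i)` is the degree of voxel *i* in the graph that
  connects every supra-threshold pair regardless of spatial position —
  exhaustive pair counting.
* **Local FCD.** For seed *i* a cluster is grown from `{i}`: a masked
  voxel *j* is added iff `C_ij > T_c` *and* *j* is neighborhood-adjacent
  (6, 18 or 26-connected; default 26) to a voxel already in the cluster;
  growth repeats to a fixed point. `lFCD(i)` is the cluster size minus
  one — the "edges" convention, since every member is by construction
  connected to the seed. Two properties follow directly and are enforced
  as tested invariants: `0 ≤ lFCD ≤ gFCD ≤ |mask| − 1`, and raising
  `T_c` never increases any count.
* **Long-range FCD** is the voxel-wise difference `gFCD − lFCD`
  (never negative on a consistent run; a negative difference aborts).

Cluster membership is defined by correlation *with the seed voxel
specifically*, not with any cluster member: the cluster is the connected
component of the seed within the subgraph induced by the seed's
supra-threshold partners. This is the literal reading of the
cluster-growing description this analysis family uses, and it makes
`lFCD ≤ gFCD` structural rather than empirical.

For group analysis the maps are variance-stabilized as
`srFCD = log(lFCD)` and `lrFCD = log(gFCD − lFCD)` (natural log; the
base is a global rescaling and cannot change any rank-based statistic
downstream), then smoothed with an 8 mm FWHM Gaussian kernel.

### Zero counts

`log(0)` is undefined and no substitution convention is universal, so
the default (`zeroHandling = "mask_missing"`) turns zero-count voxels
into missing values that are excluded from smoothing, regional means and
correlations — never silently zero-filled. A `"add_one"` option
(`log1p`) is provided as a sensitivity analysis. Raw `gFCD` is not
log-transformed in the standard pipeline; `logFcd(..., allowGfcd =
TRUE)` exposes it deliberately.

### Implementation

Correlations are computed on standardized series via BLAS matrix
products in row blocks (never materializing more than a block of the
correlation matrix), with a C++ scan for supra-threshold partners and a
C++ breadth-first cluster growing. The tests hold the implementation to
*integer-exact* equality with two independently written oracles — naive
BFS for `lFCD` and exhaustive `stats::cor` pair counting for `gFCD` —
on 50 seeded random volumes across all three neighborhoods. Zero-variance
series inside the mask are reported via a warning and treated as
connected to nothing.

## SUVR normalization and masks

A summed-uptake PET volume is divided by the mean over a white-matter
reference region. The reference is deliberately conservative: voxels
with WM probability > 0.9 whose 8 mm-smoothed GM and CSF probabilities
are both < 0.05 — i.e. deep white matter with essentially no gray or
CSF partial volume. All three criteria are strict inequalities as
conventionally printed; on continuous probability maps the boundary set
is measure-zero. The SUVR map is then smoothed (8 mm FWHM), restricted
to gray matter (GM probability > 0.10, strict) and to SUVR > 1 (strict):
at or below the white-matter level the tracer signal is treated as
nonspecific. The order — smooth, then restrict — matters at the gray
matter boundary and follows the order in which these operations are
conventionally described; restricting first would yield different edge
voxels.

Smoothing uses a separable Gaussian with per-axis
`sigma = FWHM / (voxelSize · 2 sqrt(2 ln 2))` and **zero padding** at the
volume boundary (linear, not renormalized — the common volumetric
convention). Quantitative checks therefore live on interior voxels; the
impulse response is verified to have an 8 mm measured FWHM within half a
voxel. Log-FCD maps, which carry missing values, instead use **masked**
smoothing: kernel weights are renormalized over present voxels, so a
constant map stays constant and an isolated voxel keeps its value, and
missing voxels stay missing.

The optional temporal bandpass (0.01–0.08 Hz) is a frequency-domain mask
with a raised-cosine roll-off over one frequency bin and exact DC
removal. The contract is stated in attenuation terms (≥ 20 dB outside,
≤ 1 dB well inside) so any compliant filter is interchangeable.

## Inference

Everything is rank-based. `spearmanTest()` computes ρ as the Pearson
correlation of average-tie ranks with the large-sample two-sided t
approximation `t = ρ sqrt((n−2)/(1−ρ²))`; an exact permutation p is
available for n ≤ 8. Normality checks (Kolmogorov–Smirnov against a
fully specified normal, Shapiro–Wilk) are computed for reporting only —
the pipeline never switches to parametric correlation on their outcome,
it exists to justify the rank-based choice from the data.

The group-level chain:

1. **Across regions**: Spearman ρ between regional means of the
   group-mean SUVR and FCD maps. Regional means average present voxels
   only; a region enters the across-region correlation only if both
   maps have at least `minVoxels` present voxels there (the pipeline
   uses 10 — a "regional mean" over a handful of stray voxels is not a
   regional estimate; the function default of 1 preserves the bare
   contract).
2. **Within regions**: per participant, Spearman ρ over paired present
   voxels; Fisher `z = atanh(ρ)` (|ρ| = 1 is clipped to
   `atanh(1 − 1e-7)` with a warning); the group p is a one-sample
   two-sided t test of the z values against zero. No convention for
   pooling per-participant correlations into one regional p is
   universal; the z-pooled t test is the standard choice once the
   Fisher transform has been applied, and it is what `bonferroniStep()`
   consumes.
3. **Bonferroni step**: pass iff `p < α/m`, strict, with `m` taken from
   the study design — number of regions plus number of networks (90 for
   the classic 83 + 7 design) — never from the data.
4. **Spin step**, on Bonferroni survivors only (the step order is
   enforced: a spin p is never reported for a region that failed step
   1). See below.
5. **Second level**: Spearman ρ between regional FCD magnitude and the
   regional mean z, across regions that survived both steps; regions the
   spherical projection cannot cover count as survivors on their
   Bonferroni status alone, mirroring how such regions are conventionally
   carried through.

The family-wise error of the Bonferroni step is verified by simulation:
400 null replicates of 90 region/network tests (10 participants × 20
paired values each) keep the fraction of replicates with any survivor
within `0.05 + 3·SE`.

## The spin permutation test

Parametric p-values for correlations between smooth spatial maps are
anti-conservative because neighboring samples are not independent. The
spin test builds a null that preserves each map's spatial
autocorrelation: project onto a spherical mesh, rotate the sphere,
re-assign values, recompute the statistic.

* **Mesh**: an icosahedron subdivided `order` times and projected to the
  unit sphere (10·4^order + 2 vertices per hemisphere; order 5 gives the
  familiar 10,242 per hemisphere, 20,484 bilaterally). Vertex ordering
  is deterministic.
* **Sampling**: the volume is conceptually resampled to 1 mm isotropic
  by trilinear interpolation and each vertex reads the 1 mm voxel
  containing its mm coordinate; labels use nearest-voxel reads. Missing
  volume values propagate.
* **Rotations**: angles drawn independently and uniformly on [0, 2π)
  about x, y and z, composed as `Rz Ry Rx` — exactly the printed recipe
  of the published procedure, even though that product measure is not
  the Haar-uniform measure on SO(3); `haar = TRUE` provides uniform
  rotations for sensitivity analysis. The left hemisphere receives the
  sagittally mirrored rotation `M R M`, `M = diag(−1, 1, 1)`
  (configurable off).
* **Reassignment**: each vertex receives the value of the original
  vertex nearest to its rotated position (exact nearest neighbor,
  verified against brute force; ties break to the lowest index). The
  assignment is not forced to be a bijection, so values can duplicate.
* **p-value**: one-sided, `#(null ≥ observed) / nPerm`; ties count
  against the hypothesis. An `(k+1)/(n+1)` variant exists but is off by
  default because the convention divides by exactly the permutation
  count. Only the first map is spun (the published procedure spins the
  molecular map); the statistic defaults to Spearman for consistency
  with the rest of the chain, with Pearson behind a flag.

Calibration is tested directly: with independent smooth Gaussian fields
on the sphere (squared-exponential covariance in chordal distance — the
positive-definite kernel; a geodesic squared-exponential is not valid on
the sphere), spin p-values over 200 replicates stay inside a Kolmogorov
uniformity band, while a naive value shuffle on the same fields rejects
far above its nominal level — the confound the spin exists to fix.

One published expectation is *not* met and is left failing rather than
papered over: that a rotation followed by its inverse recovers ≥ 99% of
vertex values on the order-5 mesh. With nearest-vertex reassignment the
round trip composes two independent quantizations; every vertex whose
re-rotated position crosses a Voronoi-cell boundary flips, which loses
7–9% of vertices for generic rotations (and ~2% even for a near-identity
rotation). The measured recovery here is 91–93% on an implementation
whose nearest-neighbor lookup is verified exactly; ≥ 99% would require
an optimal-assignment (bijective) spin, which is a different construction
from the one prescribed.

## The synthetic-study generator

The generator exists because the motivating data class (human receptor
PET + resting fMRI) is access-restricted. It produces, from one seed, a
full study with exposed ground truth.

**Head model.** A spherical-shell "head" on a 24³ grid of 2 mm voxels:
white-matter core (probability 0.98 inside, ramping off), gray-matter
shell (plateau 0.9), CSF outside, with probabilities in [0, 1] summing
to ≤ 1. The geometry yields a nonempty conservative WM reference and a
GM mask of ~6,000 voxels at default size.

**BOLD.** Latent-factor construction: each of 12 hub balls (radii 1–3
voxels, placed on icosahedral directions on the shell) shares a hub
latent; each of 6 long-range pairs — joining *antipodal* hubs, so the
paired balls are spatially disjoint by a wide margin — shares a pair
latent. With loadings `sqrt(rho_w − sum(rho_b))`, `sqrt(rho_b)` and noise
`sqrt(1 − rho_w)`, the planted correlations are exactly `rho_w` within a
hub (default 0.9) and `rho_b` across a pair (default 0.7); this is why
the configuration requires `rho_w ≥ Σ rho_b`, and why pairs joining
spatially adjacent hubs are rejected (touching hubs would merge into one
contiguous cluster and stop being long-range). All latent and noise
series are bandpass-shaped to 0.01–0.08 Hz at TR 2.5 s before mixing, so
the pipeline's optional bandpass is a near no-op on synthetic data.

The background noise field is spatially smoothed (`noiseSmoothFwhmVox`,
default 2.2 voxels FWHM, giving adjacent-voxel correlation ≈ 0.75).
This emulates the intrinsic spatial smoothness of real BOLD and is what
makes voxel-wise FCD well defined throughout gray matter — with strictly
independent noise, lFCD is zero (log-undefined) almost everywhere
outside hubs and within-region voxel-wise correlations have no synthetic
analogue. Setting it to 0 restores strictly independent background
noise, and the tests of the independent-noise contracts do exactly that.

**Molecular volume.** Uptake = flat gray-matter baseline + β ·
normalized planted total degree + Gaussian voxel noise (default β = 0.8,
SD 0.1), floored at a small positive value (uptake is physically
nonnegative), with the gray-matter region shifted if necessary so its
minimum exceeds the white-matter core mean — the generator's guarantee
that the SUVR > 1 restriction removes no gray-matter voxel before
smoothing. The noiseless map is exactly monotone in planted degree.

**Parcellation.** The gray-matter shell is partitioned into 16 connected
regions by multi-source breadth-first growth seeded at the hub balls
(each hub lies entirely in one region) plus random shell voxels; groups
cycle over seven canonical network names; all regions default to
spinnable.

**What it does not emulate.** Hemodynamic response shape, head motion,
scanner noise spectra, multi-site effects, anatomical variability,
partial-volume effects in PET, and any *gradient* of coupling strength
across regions (β is one number — hence the second-level correlation is
expectedly null on default synthetic data, and its power property is
tested with an explicitly constructed gradient instead). Passing tests
on this generator demonstrate algorithmic correctness and statistical
calibration, not robustness to the artifacts of real acquisitions.

One realistic feature appears on its own and is worth knowing about:
because smoothing crosses the gray-matter boundary, both SUVR and FCD
dip near mask edges, which induces a *positive* spatial confound between
the maps even at β = 0. Parametric within-region p-values respond to it;
the spin test, whose null preserves exactly this kind of shared spatial
structure, is the step that addresses it — the two-step design is not
decorative.

## Problem sizes used by the tests

Test and acceptance runs are sized for a desk machine: the reference
study uses the 24³ / 2 mm grid with 10 participants and 200 spin
permutations on an order-3 mesh; the 100-replicate recovery runs use a
20³ grid of 2.5 mm voxels (same design, same effect sizes); spin
calibration uses an order-2 mesh at 200 permutations; oracle equivalence
uses 6³ × 60 volumes. Full-scale settings (35 participants, 1,000
permutations, order-5 meshes) are reachable through the same
configuration objects.

## Degenerate inputs and tie rules, collected

* Grids must match within 1e-6 mm (shape, voxel size, origin); the first
  incompatible pair is reported with both grids. Oblique or
  axis-permuted NIfTI orientations are rejected, not reinterpreted.
* Voxel indexing is 1-based throughout (R array convention); the voxel
  centre of index `(i, j, k)` is `origin + (c(i,j,k) − 1) · voxelSize`.
* Zero-variance BOLD series inside a mask: reported, connected to
  nothing.
* Empty masks, empty regions, regions with no present voxels, fewer
  than 5 paired observations, constant inputs to correlation or
  normality tests: errors, not silent NAs.
* Spearman ties: average ranks. Spin p ties: count against the
  hypothesis. Nearest-vertex ties: lowest index. Bonferroni boundary:
  `p = α/m` does not pass.
* Study runs abort with the failing stage name; regions the spherical
  projection cannot cover are carried as "not covered", never silently
  dropped.
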