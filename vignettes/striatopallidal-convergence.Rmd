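---
title: "Methods: quantifying striatopallidal axon convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying striatopallidal axon convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## Coordinates, sections, and the data model

All coordinates are millimeters from bregma: `rc` (rostrocaudal, rostral
positive — the pallidal arborizations sit at negative rc), `dv`
(dorsoventral, dorsal positive), and `ml` (mediolateral distance from the
midline). Traced data are organized as parasagittal sections: each fiber
trace is a 2D polyline in its section's (rc, dv) plane, and a vertex's
atlas position takes `ml` from the section's mediolateral center
(`to_atlas_point()`). Fiber depth within the 20 µm section is discarded,
matching 2D tracing practice; this quantizes `ml` to the section pitch
and is the reason the mixture fit needs ridge regularization (below).

Traces carry a per-trace `varicose` flag and bouton positions as
arc-length offsets; varicosities, not bare fibers, define the terminal
field, so all density analysis defaults to varicose traces only. On disk a
dataset is a section manifest (CSV), one mask polygon per section (CSV),
a soma table (CSV), and one SWC file per trace; varicosities are encoded
as SWC type-7 leaf nodes attached to the geometry node that starts the
segment they lie on, so standard SWC viewers still render the polyline.
Round trips through `write_dataset()`/`read_dataset()` are lossless to
well below 1e-9 mm (12 significant digits are written).

Because the two fluorescence channels were traced in *separate adjacent
sections*, `superimpose_adjacent()` merges explicitly given neighboring
section pairs: the merged section takes the midpoint of the two
`ml_center`s (the unbiased choice for assigning the overlay a single
mediolateral position), the summed thickness, and the union of the two mask polygons.
Pairing is explicit input rather than inferred, because automatic
inference would guess intent. The polygon union is a Weiler–Atherton walk
valid for the convex-ish overlapping masks that section outlines are;
identical and nested masks are special-cased, and disjoint masks are an
error.

## Fiber-length density on a 40 µm lattice

The density primitive is *length per box*: each section's GPe mask is
covered by half-open 40 µm × 40 µm boxes `[x, x+s) × [y, y+s)` and every
varicose polyline segment contributes the Euclidean length of its
intersection with each box (`segment_length_in_box()`, parametric
Liang–Barsky clipping). Design choices the source analysis left open:

* **Lattice origin.** The mask bounding box floored to `box_size`
  multiples — a global-grid alignment, so both channels of a section (and
  refinements by halving `box_size`) always share lattice lines.
* **Half-open boxes.** A vertex or edge-riding segment belongs to the
  higher-index box only; summed box lengths equal the clipped polyline
  length exactly (tested to 1e-6 relative against an independent
  clipper).
* **Mask clipping precedes boxing.** A segment partially outside the GPe
  contributes only its inside part; boxes outside the mask therefore
  never acquire entries.
* **Presence.** For overlap classification a box is "present" in a
  channel when its length exceeds a threshold, default 0 mm (strictly
  positive); the threshold is exposed because sub-box noise levels are
  data-dependent.

`grid_to_weighted_points()` turns a grid into one 3D point per nonempty
box — (box rc-center, box dv-center, section ml) weighted by box length —
conserving total weight exactly. This weighted point set is the fit input:
box-center quantization adds variance `s²/12` per in-plane axis (~3% of
the component variance at the defaults) and the section pitch does the
same in ml; both are small against the fiber-sampling noise discussed
below.

## The two-component arborization model

Each channel's density is modeled as exactly two trivariate Gaussians
(K = 2 fixed — the phenomenon under study is two arborizations; no model
selection). `fit_two_gaussians()` runs EM on the weighted log-likelihood
`Σᵢ wᵢ log Σₖ πₖ N(xᵢ; μₖ, Σₖ)` with weights entering the E-step
responsibilities and every M-step sum. Numerical choices:

* **Initialization** splits the points at the weighted median rc (ties
  broken by dv, ml, weight), seeding each half's weighted moments. The
  arborizations are rostrocaudally arranged, so this is both apt and
  fully deterministic; `restarts > 1` adds random restarts, best final
  likelihood wins.
* **Ridge.** `1e-6 mm²` is added to covariance diagonals every M-step:
  with only ~0.02 mm section pitch, the ml marginal would otherwise go
  near-singular.
* **Convergence** when the weighted log-likelihood improves by less than
  `tol = 1e-8` (or 500 iterations); the likelihood trace is kept and its
  monotonicity asserted in tests.
* **Labels.** "#1" is the component with the larger rc mean (rostral),
  ties broken by dv, then ml, then weight. Label assignment is invariant
  to input order because the initialization is.

`mahalanobis_region(component, r)` returns the ellipsoid
`(x−μ)ᵀΣ⁻¹(x−μ) ≤ r²` (axes = covariance eigenvectors, semi-axes
`r·√λ`), and `section_ellipse()` its exact cut by a section plane for
overlay plots. `mass_within(r, d) = pchisq(r², d)`: at r = 1 in 3D the
contour holds 19.87% ≈ 20% of the component mass, which is what makes the
unit-Mahalanobis ellipse a sensible "core of the arborization" summary.

## Convergence statistics

`center_distances()` pairs labels across channels (G1–R1, G2–R2) and
within channels (G1–G2, R1–R2). For a cohort, the two within-channel
distances per mouse pool into one sample and the two cross-channel
distances into the other (2n vs 2n values for n mice) — the densest
pooling available from a cohort — `pool_distances()` implements it and per-mouse averaging
remains available by aggregating first. `ks_compare()` uses the exact
two-sample Smirnov distribution whenever `n·m ≤ 10⁴` (12-vs-12 is far too
small for the asymptotic formula) via `stats::ks.test`; tests check it
against exhaustive enumeration of all `C(n+m, n)` splits.

`classify_boxes()` binarizes both grids on the shared lattice and counts
GFP-only / RFP-only / both boxes; percentages use occupied boxes as the
denominator (boxes empty in both channels are not part of the projection
area). `overlap_percentages()` aggregates per-mouse percentages as an
unweighted mean ± SD (n−1), flagging single-mouse cohorts.
`projection_extent()` reports per-axis max−min of mask-clipped varicose
vertices, with the ml extent spanning the touched section centers.
`contingency_percentage()` rounds half-up to one decimal, the convention
used for published co-labeling counts (255/258 → 98.8).

## Topography

`soma_summary()` gives per-channel soma centers and ranges;
`topography_report()` regresses, for each axis and each arborization
label, the soma center (vertical axis, the conventional plot orientation
for injection-site vs projection-site comparisons) on the fitted arborization center, pooling the two channels
as separate points (12 points for 6 mice; per-channel regressions are
also computed). `axis_regression()` is OLS with the Pearson r and its
two-sided t-test p (n−2 df). Slope *recovery* checks in the tests use the
generative direction (arborization center on soma center), which is the
direction the synthetic topographic map is defined in; single-cohort
slopes scatter with SD ≈ 0.05 at 6 mice, so recovery is judged on the
mean over replicate cohorts.

## What the synthetic generator emulates

`synth_config()` defaults encode the study conditions; each mouse is
generated from named substreams (somata / fibers / cohort) of a single
seed, so identical (config, seed) reproduce identical bytes on disk.

* **Somata**: 29 GFP / 22.8→23 RFP cells (the reported means), Gaussian
  around `soma_center = (0.5, −3.0, 2.2)` mm with per-axis SDs
  (0.13, 0.20, 0.135) mm — chosen so the expected range of ~25 draws
  (≈3.9 σ) reproduces the reported 0.52/0.80/0.53 mm soma-cloud ranges in
  a ~0.5 × 0.8 × 0.5 mm injection volume.
* **Arborizations**: per channel a two-component mixture; the mid-center
  is the topographic image of the soma center under `topo_map` (slopes
  0/1/1, so dorsoventral and mediolateral topography but none
  rostrocaudally), and components sit at ±(0.10, 0.10, 0) mm around it —
  centers (−0.35, −3.2, 1.9) and (−0.55, −3.4, 1.9) at the default
  injection, inside the reported −0.3…−0.6 mm rc interval. Component SDs
  (0.07, 0.10, 0.10) mm are back-computed from the reported
  projection-field extents; the RFP covariance is 1.5× the GFP one,
  making the indirect-pathway field wider, and cross-channel centers
  coincide exactly (the convergence ground truth).
* **Fibers**: 80 GFP / 120 RFP fibers of Gamma(4)-distributed length
  (mean 2.0 mm — single MSN pallidal arbors carry millimeter-scale
  cable), realized as stationary AR(1) (discrete Ornstein–Uhlenbeck)
  walks whose per-axis stationary law *is* the sampled component
  Gaussian: every vertex is marginally N(μ, Σ) while consecutive vertices
  stay ~`fiber_step` = 10 µm apart. This realizes the target density as
  genuine polylines — so length-based gridding, clipping, and
  superposition are actually exercised — rather than as i.i.d. points.
  The ml step is kept smaller (4 µm) than the in-plane step: axons run
  mostly within a parasagittal plane, and this keeps section fragments
  several vertices long.
* **Varicosities**: exponential arc-length spacings (mean 6 µm) — the
  memoryless choice, since no bouton statistics were reported. 80% of GFP
  fibers are varicose and all RFP fibers are (non-varicose GFP fibers
  exist in the traced data and are excluded from density analysis).
* **Sections and mask**: 20 µm sections spanning ml 1.3–2.7 mm; one
  elliptical GPe-like mask (semi-axes 0.55 × 0.70 mm) centered on the
  arborization mid-center, generous enough that clipping touches only
  fiber tails.
* **Cohorts**: `generate_cohort()` displaces each mouse's injection
  center by a per-axis Gaussian jitter (default 0.15 mm) and rederives
  the arborization centers through `topo_map`, embedding a known linear
  topography for recovery tests. `generate_colabel_counts()` draws
  binomial co-labeling counts.

**What it does not emulate** — and hence what passing tests do and do not
show about real data: no biophysical axon growth, branching, or dendrite
geometry; no tracing errors, missed boutons, or section-registration
error; masks are identical across sections rather than anatomically
varying; fiber density is stationary Gaussian rather than following
internal GPe compartments (e.g. calbindin-rich vs -poor zones). Tests
passing on this generator validate the *measurement chain* — gridding,
fitting, statistics — under known ground truth, not the biological
fidelity of any particular mouse.

A statistical consequence of realistic fibers worth knowing: a fiber's
AR(1) correlation length is comparable to its own length, so each fiber
contributes roughly one effective sample to its component. Component
centers therefore carry ~0.03–0.05 mm estimation error at the default
fiber counts, covariances ~30% relative Frobenius error — both shrink as
`1/√n_fibers` (tests verify the scaling). All recovery tolerances in the
tests are set against this fiber-level sampling floor, with per-fiber
(cluster-robust) standard errors wherever moments are compared, because
points along one fiber are far from independent.

## Problem sizes and determinism in the test suite

Unit tests run on reduced configurations (15–22 fibers, 0.8 mm span);
the acceptance-style tests run the full default conditions: one hundred
6-mouse replicate cohorts feed the KS convergence property, the first
fifty of them the overlap-ordering, set-operation-oracle, and
null-rc-topography properties, twenty single mice the center-recovery
property, and one thousand random segments the dense-sampling clipping
oracle. Every stochastic step is seeded; `run_pipeline()` embeds the
config hash and seed in every artifact and identical config + seed
reproduce `report.json` byte for byte.

## Known limitations

* The polygon union supports convex-ish overlapping masks — adequate for
  section outlines, not a general boolean engine.
* K = 2 is fixed; a mouse whose field is genuinely unimodal will still be
  decomposed into two components (the convergence diagnostics — weights,
  likelihood trace — are the intended way to notice this).
* Exact KS p-values are computed for `n·m ≤ 10⁴`; above that the
  asymptotic formula is used.
* `ml` resolution is bounded by the section pitch; covariances in ml are
  correspondingly coarse, which the ridge absorbs but does not remove.
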