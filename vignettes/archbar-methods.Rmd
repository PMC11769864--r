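---
title: "Bar-based full-arch scan metrology: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bar-based full-arch scan metrology: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archbar)
```

## Why a reference bar

Full-arch scans from intraoral scanners are assembled by stitching small
optical frames; stitching errors accumulate with scan-path length, so the
cross-arch error of the final mesh is the quantity of clinical interest
(it determines whether a cross-arch restoration will fit). The common
evaluation approach — best-fit superimposition of a test mesh on a
reference mesh — minimizes exactly the residuals one wants to measure and
can therefore hide systematic misalignment. `archbar` instead measures real
geometric quantities on a reference object: a bar of certified length
spanning the arch, of which only the two ends are captured (at most 20 mm
each), deliberately preventing the scanner software from bridging the bar
itself.

## The per-scan measurement model

Each scan is re-expressed in a model frame (X transversal along the bar,
positive toward the first quadrant; Y anterior; Z vertical). Six planar
regions of the bar ends are selected by declarative geometric selectors
(oriented boxes stored in the configuration, replacing interactive surface
picking) and a plane is fitted to each by orthogonal least squares: the
plane through the centroid whose normal is the smallest-eigenvalue
eigenvector of the centered second-moment matrix. This is the standard
"contact feature" analogue in inspection software; the inspection software
used in practice does not document its fitting tolerance or orientation
rule, so both are defined explicitly here (see *Numerical choices*).

The constructions are pure incidence geometry: the anterior and posterior
planes of each end intersect in the upper bar edge (V1, V2); each edge
meets its vestibular end plane in a reference point (P1, P2); the second
vestibular plane is parallel-shifted by the certified length toward the
first quadrant and meets V2 in the constructed point P2′. The deviations
are `V_E = P1 − P2′` (componentwise, µm), `ΔL = |P2 − P1| − L` (µm), and the
three angles between the edges: the full 3D angle `α_overall`, and its two
printed-formula projections `α_coronal` (X, Y components) and `α_axial`
(X, Z components). A perfect scan yields exactly zero for all of them.

Two conventions deserve comment:

- **ΔL** is not defined anywhere beyond its tabulated values in the source
  study; `archbar` defines it as the measured P1–P2 distance minus the
  certified length, which is the only length-like measure consistent with
  ΔL tracking the X component of `V_E` for an X-aligned bar.
- **`|V_E|`** is reported as the Euclidean norm of the error vector: the
  only nonnegative scalar that dominates each of its components.
- The names `α_coronal` / `α_axial` follow the field's usage even though
  the "coronal" projection uses the (X, Y) components and the "axial" one
  (X, Z); the formulas are implemented exactly as printed and the naming
  inconsistency is deliberately not resolved here.

### Frame alignment

The source workflow "virtually adjusts" each scan in a coordinate system
without stating the procedure. `archbar` defines alignment operationally:
the configuration carries a reference frame (origin plus orthonormal
right-handed axes, default identity) and every mesh is re-expressed in it
before analysis. Any consistent frame choice preserves the deviation
magnitudes — a property the test suite verifies by transforming a whole
mesh rigidly and supplying the matching frame, which leaves `|V_E|`, ΔL and
all angles unchanged to 1e-6. Signed `V_E` components are only comparable
between scans analyzed in the same frame.

## The synthetic generator

No scan data ship with the package, so the generator is the ground-truth
side of every end-to-end test. It emulates:

- a bar of certified length (default 55.066 mm) whose outer end faces are
  *exactly* that far apart, with at most 20 mm of each end meshed
  (default 18 mm) — the study's capture rule;
- a rhombic (diamond) bar cross-section (default 6 mm × 6 mm), so that the
  anterior and posterior faces meet in the upper edge the constructions
  measure. The physical reference object is a precision square: its
  anterior/posterior surfaces likewise meet in an edge, which is what makes
  the AP ∩ PP intersection well-posed;
- an arch ribbon connecting the ends (cosmetic: it provides off-bar
  vertices so region selection is meaningful, but carries no anatomy —
  tooth shape is irrelevant to the measurands);
- a per-scan distortion: a rigid transform of the entire second bar end
  (rotation about the end centroid, then translation), emulating the
  accumulated cross-arch stitching error, plus isotropic Gaussian vertex
  noise emulating surface measurement noise;
- strategy profiles: each of the nine strategies (F/H/S × L/Z/C) draws its
  per-scan translation and rotation components from independent normals.
  The default locations and scales are configuration values on the
  magnitude scale typical of full-arch scans (tens to a few hundred µm,
  tenths of a degree, larger for zig-zag and sextant strategies); they are
  modelling inputs, not empirical claims.

What the generator does *not* emulate: the optical acquisition itself
(triangulation/confocal imaging), frame-level stitching, scanner-specific
artifacts (holes, spikes, texture-dependent noise), or smooth whole-arch
warps. A rigid per-end error is identifiable from the bar measurands and
is exactly invertible, which is what makes closed-form recovery testing
possible; passing those tests shows the *pipeline* is correct, not that
real scanners err rigidly.

The fast simulation path skips meshing entirely: it draws the distortion
parameters and propagates them in closed form through the same
plane/line constructions. It is used for statistics-layer testing and the
study-scale design (9 × 25 = 225 records in well under a second). Vertex
noise only acts in the mesh path.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bar_length_mm` | 55.066 | mm | certified reference length of the bar |
| `captured_end_length_mm` | 18 | mm | below the 20 mm capture ceiling |
| `bar_width/height_mm` | 6 | mm | precision-bar scale cross-section |
| `resolution_mm` | 0.4 | mm | target mesh edge length; the coarsest scanner-plausible triangle density (real intraoral meshes are 0.05–0.2 mm) that keeps test-time mesh analysis fast |
| `noise_sigma_um` | 5 | µm | per-coordinate vertex noise, modern-scanner surface noise scale |
| `family_alpha`, `m` | 0.05, 3 | — | Bonferroni family of 3 comparisons within one design factor level; 0.05/3 reported as 0.017 |

Resolution interacts with two things worth knowing. First, plane-fit noise:
fitted-normal error scales like σ/(√n·extent), and the edge points are
evaluated at the end of the captured face, so coarse meshes amplify vertex
noise into the recovered points. Second, the vestibular end-face selector:
its thickness is half the axial grid step (it must exclude the first
side-face grid line), which bounds the tolerated end translation along X to
about `resolution_mm / 2`; the validation distortions (≤ 0.12 mm) are well
inside that at the default resolution.

## Statistical layer

- **Descriptives** per strategy and parameter: mean, sample SD (n − 1),
  median, min/max and the **t-based 95% CI** `M ± t(0.975, n−1)·SD/√n`.
  The CI method is never named in the source tables; the t convention is
  adopted because it reproduces the published bounds from the published
  (M, SD, n = 25) to the printed precision, which the acceptance suite
  recomputes.
- **Normality**: Shapiro-Wilk (the flagging test) plus Kolmogorov-Smirnov
  in two flavours — the Lilliefors variant (estimated parameters, the
  composite hypothesis actually at stake) and the plain plug-in KS —
  because the source does not say which was used.
- **Trueness comparisons** on the signed deviations: Kruskal-Wallis
  (tie-corrected H, χ² reference) across groups, pairwise two-sided
  Mann-Whitney below the Bonferroni threshold. Exact p values are used for
  tie-free pairs with min(n) ≤ 8, the normal approximation with continuity
  and tie correction otherwise.
- **Precision** per ISO 5725-1 is summarized by the SD; pairwise
  differences are tested with Brown-Forsythe (Levene on absolute deviations
  from group medians), chosen because it is robust to the non-normality the
  deviations typically show; the source marks precision letters without
  naming any test.
- **Compact letter display** by insert-and-absorb: groups share a letter
  iff their pairwise comparison is non-significant (uppercase trueness,
  lowercase precision); the equivalence is re-verified directly on every
  generated report in the test suite.

Degenerate conventions: a set of groups with no variation at all yields
H = 0, p = 1; dispersion comparison of identical dispersions yields p = 1;
normality tests refuse constant samples.

## Numerical choices

- Parallelism cutoffs at 1e-6 on normalized cross/dot products; geometric
  incidence assertions at 1e-9 mm — appropriate for double precision at
  mm-scale coordinates.
- The arccos argument is clamped to [−1, 1] to absorb floating-point
  overshoot.
- Sign conventions: plane normals are oriented by a caller-supplied outward
  hint; line directions take positive X component (falling back to Y, then
  Z). Without such a convention the arccos-based angles would report ~180°
  for flipped directions, whereas physical torsions here are < 3°.
- Plane-fit residual is computed from the projections onto the fitted
  normal, not from the smallest eigenvalue, which carries the
  eigen-decomposition's absolute error.
- Vertex merging at 1e-9 mm on STL load; zero-area facets dropped.
- Binary STL stores float32, which at ~50 mm coordinates quantizes at the
  µm scale; the ASCII dialect is written with full double precision and is
  the one used where sub-µm exactness matters. Units are fixed to mm (STL
  carries none).

## Problem sizes used in the tests

The shipped suite analyzes meshes of ~1.5k vertices (1.0 mm resolution)
for geometric identities that hold exactly at any resolution, and the
default ~8.6k-vertex model for noisy parameter recovery (25 replicates per
injected distortion). Statistical calibrations use 200–1000 repetitions at
the study's group size n = 25. These sizes keep a full run around a minute
while leaving the stochastic checks comfortably inside their bands.

## Known limitations

- The rigid-end distortion model is a stand-in with recovery-testing value;
  it says nothing about how any particular scanner actually deforms a mesh.
- Region selectors assume the configuration frame roughly matches the scan;
  grossly misaligned scans fail with an insufficient-region error rather
  than being auto-registered (mesh registration is out of scope by design).
- Signed `V_E` components depend on the frame convention; only magnitudes
  are frame-invariant.
- The Bonferroni family (m = 3) matches comparing the three levels of one
  design factor; analyses pooling all 36 pairs of a 9-group study should
  set `m` accordingly.
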