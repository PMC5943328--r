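---
title: "Designing functionally graded TPMS bone scaffolds: models, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing functionally graded TPMS bone scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmscaffold)
```

## The problem

Bone-defect repair scaffolds must mimic cancellous bone, whose trabecular
architecture varies regionally: load-bearing regions are built from thick
plate-like trabeculae, other regions from thinner rod-like struts with more
uniform pores. A scaffold that is homogeneous throughout cannot match both.
This package implements a design pipeline for *functionally graded* porous
scaffolds: triply periodic minimal surface (TPMS) lattice units with
different wall thicknesses and topologies are placed in different regions
of one part and fused smoothly, the resulting geometry is exported as a
printable STL mesh, and the same morphometric and mechanical measurements
that characterize real trabecular bone (porosity, trabecular
thickness/separation, surface area density, structure model index,
apparent elastic modulus, von Mises stress) are computed on the design so
it can be matched to target bone properties.

## Implicit scaffold geometry

### Nodal TPMS fields

A nodal TPMS is the level set of a short trigonometric sum

$$\phi(\mathbf r) = \sum_k A_k \prod_{i \in \{x,y,z\}}
  f_{k,i}\!\left(n_{k,i}\,\theta_i + p_{k,i}\right) = C,
\qquad \theta_i = \frac{2\pi r_i}{a},$$

with per-axis factors $f \in \{\cos, \sin, 1\}$, integer frequency
multipliers $n$, phases $p$, amplitude $A_k$, and level constant $C$.
`tpms_preset()` provides the classical P, D and gyroid (G) units and two
*tubular gyroid* bone units, TGab and TGc, which add second-harmonic
product terms and a constant offset to the gyroid skeleton:

$$\mathrm{TG}_{ab} = 20(\cos X \sin Y + \cos Y \sin Z + \cos Z \sin X)
 - 0.5(\cos 2X \cos 2Y + \cos 2Y \cos 2Z + \cos 2Z \cos 2X) - 4,$$

and TGc with coefficients $(10, -2, -12)$. TGab emulates the coarse
plate-like peripheral regions of the femoral condyle, TGc the finer, more
isotropic medial region.

Conventions chosen here, applied uniformly:

* **Physical coordinates.** All presets take millimetre coordinates and
  map one period onto `cell_size` on every axis, including the TG units
  (which are classically written in raw radians with period $2\pi$). This
  gives `cell_size` the same physical meaning for every unit.
* **Constant offsets live in the term sum.** The TG offsets ($-4$, $-12$)
  are stored as constant terms, so every preset's surface is the zero
  level set and `eval_field()` returns the full printed expression (e.g.
  TGab at the origin evaluates to $-5.5$).
* **Solid phase is $\{\phi \le C\}$.** The sign convention is not fixed by
  the mathematics; this choice makes a larger level constant produce more
  solid for P-like fields, which reads naturally when tuning wall
  thickness ("raise the level to thicken").
* **Voxel sampling at cell centers.** `sample_grid()` samples half a voxel
  inside the domain corners so both domain faces are treated
  symmetrically; the gyroid then recovers its exact half-half labyrinth
  split at any even resolution.

### Sigmoid fusion of heterogeneous units

Two units $\phi_1, \phi_2$ are fused by a logistic weight of a transition
boundary function $G(\mathbf r)$:

$$\phi_{sf} = \alpha\,\phi_1 + (1-\alpha)\,\phi_2, \qquad
  \alpha = \frac{1}{1 + e^{-k\,G}},$$

so unit 1 dominates where $G > 0$, unit 2 where $G < 0$, with a smooth,
monotone transition across $G = 0$ whose width is set by the steepness $k$
(for a unit-gradient boundary the weight moves from 0.12 to 0.88 over
$\approx 4/k$ mm). Plane, sphere and general quadric boundaries are
supported. Because the blend is a pointwise convex combination, fusing a
unit with itself reproduces it exactly, and off the boundary the blend
converges to the sign-selected unit at the sigmoid tail rate
$e^{-k|G|}$ — both properties are enforced in the test suite.

Two design choices were genuinely open:

* **Levels are subtracted before blending.** If the two units carry
  different level constants, blending the raw values would mix
  incompatible iso-levels; the package blends $\phi_i - C_i$, so the fused
  surface is always $\{\phi_{sf} = 0\}$.
* **More than two units cascade pairwise** (`multi_blend()`), each new
  unit claiming its own $G<0$ region. The cascade is order-dependent near
  triple junctions; this is documented rather than hidden, since a
  canonical n-ary generalization does not exist.
* **Default steepness** is $k = 2\pi/\text{cell\_size}$, which confines
  the visible transition band to roughly one unit cell — wide enough to
  avoid wall discontinuities, narrow enough to keep the regional units
  recognizable. It is a starting point, not a constraint; `transition_spec()`
  takes any $k > 0$.

## Meshing

Surfaces are extracted from sampled fields by the tetrahedral
decomposition variant of marching cubes: each grid cell is split into the
six Kuhn tetrahedra sharing the cell's main diagonal, and the isosurface
is interpolated linearly on tetrahedron edges. The Kuhn split tiles space
compatibly (adjacent cells agree on the shared-face diagonals), and a
tetrahedron has no ambiguous sign configurations, so the extracted
surface is consistent and capped meshes are watertight by construction —
properties the test suite checks for every preset at several resolutions.
Triangles are wound so normals point out of the solid.

Closed ("capped") meshes for printing are produced by padding the volume
with one exterior layer before extraction. The pad reflects solid
boundary samples through the iso-level, which places the interpolated cap
exactly on the domain face, so enclosed volumes match voxel solid volumes
closely (the gyroid at $64^3$ agrees to about $10^{-3}$ of the box
volume). One half-voxel-scale artifact remains and is documented rather
than patched: where two caps meet at a box edge the interpolated surface
chamfers the corner, so the area and volume of box-like solids converge
to their exact values at first order in the voxel size.

STL input and output implement both dialects (binary: 80-byte header,
`uint32` count, 50-byte facet records; ASCII: `facet normal`/`vertex`
blocks). Binary coordinates are single precision by format; round trips
preserve triangle count exactly and coordinates to float32 resolution.

## Trabecular morphometry

All metrics operate on a `binary_volume` (solid mask + spacing), real or
synthetic:

* **Porosity / BV·TV$^{-1}$** — voxel counting.
* **Trabecular thickness (TT) and separation (TS)** — model-independent
  local thickness: the value at a voxel is the diameter of the largest
  sphere lying entirely in the phase (solid for TT, pore for TS) that
  covers the voxel, computed from an exact Euclidean distance transform
  with distance-ridge pruning and sphere painting. Following common
  practice in bone image analysis the image border is *not* a phase
  boundary (spheres may stick out of the box), so spanning structures are
  not artificially thinned; the radius is calibrated as the raw
  center-to-center distance, which recovers analytic plate and gap widths
  to within a voxel. On digitized curved bodies (rods, spheres) the
  surface shell carries an unavoidable deficit of one to two voxels.
* **Surface area density (SAD = S/BV)** — the solid surface is meshed
  (below) and the area of the domain-boundary caps is excluded, so a
  volume-filling solid has SAD exactly 0 and a spanning plate contributes
  only its two free faces. S/TV is reported alongside.
* **Structure model index (SMI)** — $6 V S' / S^2$ with $S'$ the surface
  area derivative under an infinitesimal outward offset, estimated by a
  central difference at half a voxel: mesh vertices are displaced along
  outward vertex normals accumulated from non-cap triangles. Ideal plates
  give 0, rods 3, spheres 4.

Two numerical choices matter for the surface metrics:

* **Mask pre-smoothing.** Isosurfacing a raw binary mask yields staircase
  facets whose area overestimates the true surface. The mask is smoothed
  with a Gaussian of $\sigma = 1$ voxel before extraction; on analytic
  phantoms this recovers plate, rod and sphere areas to a few percent at
  $96^3$–$128^3$ while shifting interfaces by well under a voxel. The
  $\sigma$ is exposed (`smooth_sigma`) for volumes with very thin
  features.
* **Cap handling at spanning structures.** Cap-adjacent "junction"
  slivers (interpolation artifacts within half a voxel of a box face)
  would otherwise pollute $S'$; triangles whose vertices all lie within
  0.55 voxel of one face plane are classified as cap, and within a
  0.6-voxel band along the faces the dilation offset is projected tangent
  to the face — dilating a spanning plate or rod keeps it spanning. With
  these choices the discretized plate phantom reports SMI exactly 0, the
  rod 2.97 and the sphere 3.98 at $128^3$ (computed by
  `scripts/acceptance.R` and the test suite).

## Voxel homogenization

Mechanical matching uses image-based linear elasticity:

* **Material model.** Micro-CT gray values map affinely to apparent
  density through two calibration references
  (`density_from_gray()`), and density maps to modulus by the cancellous
  bone power law $E = 6850\rho^{1.49}$ MPa for $\rho \le 1.68$ g/cm³ and
  $E = 4239\rho^{2.39}$ above — implemented exactly as printed, including
  the small discontinuity at the branch point (14839 vs 14647 MPa), with
  the boundary value assigned to the low-density branch. Elements at or
  below 5 MPa receive the air-like floor of exactly 0.01 MPa
  (`apply_floor()`); Poisson's ratio is 0.3 throughout.
* **Solver.** One trilinear hexahedral element per voxel, a single
  reference stiffness matrix scaled by the per-voxel modulus, matrix-free
  Jacobi-preconditioned conjugate gradients (relative residual
  $10^{-8}$). A $32^3$ problem solves in seconds on one core.
* **Loading protocol.** Displacement-controlled uniaxial compression at
  1% strain along each of the three orthogonal directions: the loaded
  face receives a uniform normal displacement (tangentially free by
  default, a fully clamped variant is available), the opposite face is
  fully fixed, lateral faces are traction-free. The apparent modulus is
  reaction force / (loaded area × strain); the von Mises summary averages
  over load-bearing voxels (modulus above the floor).

The boundary-condition details are deliberately validated only through
closed forms that do not depend on them: with $\nu = 0$ a uniform block
returns its own modulus and a two-layer series laminate the harmonic mean
(both exact in the tests), a cubically symmetric phantom is equally stiff
in all three directions, and scaling all moduli scales all outputs
linearly. With $\nu > 0$ the clamped support induces genuine end effects
(a uniform block reads a few percent stiff), which is a property of the
protocol, not a solver error.

## Parameter tuning

`fit_level_to_porosity()` automates matching scaffold porosity to a
target: porosity is verified monotone in the level constant over the
bracket, then bisected to an absolute porosity tolerance (default 0.005).
The field is sampled once and re-thresholded per iterate, so fits are
deterministic. `fit_to_modulus()` closes the loop through the voxel
solver: one free parameter (level constant or a global amplitude scale —
both are plausible "structural parameters", so both are exposed) is
bisected until the homogenized apparent modulus reaches the target within
a relative tolerance (default 2%), with a coarse pre-scan that detects
non-monotone responses and falls back to the first bracketing
sub-interval with a warning. Fitting runs at reduced resolution by
default ($32^3$) because each iterate costs one solve; a final check at
production resolution is recommended.

## Synthetic phantoms

`make_phantom()` generates the analytic geometries every other module is
tested against: spanning plates, mirror-symmetric plate arrays, spanning
rods, interior spheres, and gyroid blocks, voxelized by center inclusion
so the stored ground truth (porosity, TT/TS, SAD, SMI) is exact geometry
at any resolution. `render_grayscale()` adds the imaging layer — gray
assignment, Gaussian partial-volume blur, additive noise under an
explicit seed — so segmentation can be exercised against known truth.
What the phantoms deliberately do *not* emulate: real trabecular
interconnection topology, CT beam hardening, ring artifacts, or spatially
varying noise. Passing phantom tests therefore validates the metric
implementations and their discretization behavior, not the biological
variability of real scans.

`make_gradient_demo()` assembles the reference end-to-end artifact — a
TGab | TGc | TGab stack fused by two plane transitions, sampled,
binarized, capped-meshed, and summarized — and is itself under test
(watertightness, symmetric non-constant porosity profile, complete
morphometry report).

## Problem sizes and limitations

The test suite runs phantoms at $32^3$–$128^3$ and solves elasticity at
$10^3$–$32^3$, sizes chosen so the whole suite completes in about a
minute on one core while every criterion is measured at the resolution
its tolerance was specified for. Known limitations:

* Thickness metrics on curved digitized bodies are biased low by up to
  about two voxels (surface-shell effect of sphere fitting); refine the
  grid rather than re-calibrating when this matters.
* The SMI dilation derivative relies on the cap/tangency treatment at
  spanning structures; for objects whose genuine surface hugs a box face
  within half a voxel, that band is misattributed to caps.
* The cascade blend is order-dependent near triple junctions.
* The solver is small-strain linear elasticity with a shared Poisson
  ratio; no damage, contact or large deformation.
* Homogenization assumes isotropic voxels and at least $8^3$ elements.
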