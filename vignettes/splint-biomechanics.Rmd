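---
title: "Occlusal splint biomechanics with splintfea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusal splint biomechanics with splintfea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parafunction of the masticatory muscles (bruxism) overloads the teeth and
periodontal tissues. A standard treatment is a removable occlusal splint —
a PMMA appliance covering the dentition that changes both the magnitude and
the distribution of the occlusal force. `splintfea` models the mechanical
consequences for the mandibular dentition in three scenarios:

* **Option 1** — no splint: each tooth carries its own measured share of the
  occlusal force;
* **Option 2** — splint as manufactured: the total force acts on the splint
  top and is transmitted to the crowns through bonded contact;
* **Option 3** — splint after corrective grinding: same mechanics as
  option 2 but with the force magnitude and distribution re-measured after
  the correction. Grinding is represented *only* through the changed
  measurement; the splint geometry itself is not altered.

The package covers the whole chain: calibration of relative intraoral
pressure-sensor (T-Scan) readings into absolute Newton forces, generation of
a synthetic dentition (a stand-in for patient CT data, which is not
distributable), linear-elastic finite-element solution, and safety
post-processing.

## Force calibration

A T-Scan acquisition yields a dimensionless total ("raw sum") and per-tooth
percentage shares. The absolute force follows the linear calibration

$$F = 0.021 \times \text{raw sum} + 8.022 \; [\mathrm{N}],$$

and per-tooth forces are the percentage shares applied to $F$ without
renormalisation. All internal arithmetic is unrounded; one-decimal rounding
(half away from zero) is applied only at report emission, matching the
precision of published occlusal-force tables. Side and group shares intended
to be compared against published percentages are computed from the
one-decimal table (`round_distribution()`), because published side splits
are consistent with the rounded per-tooth values rather than with the exact
products. With exact shares the left/right split of the post-grinding
measurement is 50.0/50.0; from the rounded table it is 50.1/49.9, matching
the published value.

Three bundled measurements (`tscan_measurement(1:3)`) carry the raw sums
11873, 5643 and 7801 and the corresponding per-tooth shares.

## Synthetic dentition

No patient geometry ships with the package, so all FE work runs on a
parametric stand-in built by `dentition_spec()` + `mesh_dentition()`:

* **Teeth.** Axisymmetric solids: a conical-frustum crown (widening from the
  cervical radius at the gum line to the full crown radius at the flat
  occlusal plane) and a tapered root with a blunt tip. Fourteen teeth are
  placed on a semicircular arch, spaced by their half-widths plus a fixed
  0.6 mm gap.
* **PDL shells.** Each root is wrapped by a periodontal-ligament shell of
  physiological thickness 0.25 mm, generated as the offset band of the root
  surface only (the crown carries no PDL). Shell construction fails loudly
  if a shell would touch a neighbouring tooth.
* **Splint.** A single connected solid: an occlusal slab of uniform
  thickness resting directly on the crown-top plane (zero gap, as a
  well-fitting appliance is assumed to seat), plus walls that embrace each
  crown and fill the embrasures.
* **Phantom.** `generate_phantom()` rasterises the same solids into a
  0.20 mm voxel Hounsfield grid — enamel-like teeth in [2700, 3000] HU, a
  bone band in [150, 1800] HU below the gum line, soft tissue below 150 HU —
  so the threshold-segmentation step (`segment_phantom()`) can be exercised
  end to end. Because bone genuinely overlaps the generic 1000–3000 HU tooth
  window, isolating the 14 teeth requires raising the lower limit (2000 HU
  in the tests), which mirrors why clinical segmentation at 1000 HU needs
  manual editing.

**Scale.** The default teeth are deliberately miniaturised (crown 2.2 mm,
root 3.6 mm, widths 1.7–2.2 mm) rather than life-size. The reason is the
meshing strategy: a single conforming background grid must resolve the
0.25 mm PDL shell, which caps the cell size at about 0.25 mm; life-size
teeth at that resolution would produce millions of elements, while the
miniature arch yields roughly 5 × 10⁴ elements without the splint and
10⁵ with it — sizes a plain-R sparse solver handles in seconds to minutes.
The consequence, stated plainly: **absolute displacement and stress
magnitudes are not comparable to any patient case.** The published
patient-specific maxima cannot be reproduced without the CT geometry, and
the package does not attempt to. What the synthetic model does support are
the *mechanical properties* of the system — load conservation and
equilibrium, decoupling of teeth without the splint, redistribution of load
to unloaded teeth through the splint, linear scaling in load and stiffness,
and the location of stress concentrations — which are scale-free.

## Meshing

`mesh_regions()` uses a structured background grid: every region is
rasterised on one shared cubic grid (cell size `min(max_edge)/sqrt(3)`, so
the cell diagonal — the longest edge of the decomposition — respects the
smallest per-region edge-length target), and every cell whose centroid lies
inside a region is split into the fixed six-tetrahedron Kuhn pattern. This
trades geometric smoothness (surfaces are staircases) for three properties
that matter more here: determinism, guaranteed positive element volumes,
and automatic node conformity across region interfaces, which turns bonded
tooth–PDL and crown–splint contact into simple node sharing. Node sets are
rebuilt from the mesh: occlusal sets are region-boundary faces whose
outward normal is within 30° of vertical near the crown-top plane (the
same rule, applied to the splint region, defines the splint-top set), and
the fixed set `pdl_outer` is the PDL boundary on the global mesh surface —
the interface towards the alveolar bone, which is intentionally not
modelled.

With one shared grid, per-region edge-length targets collapse to the finest
one. The defaults therefore use a single 0.45 mm target (cell ≈ 0.26 mm)
for all regions, chosen to resolve the PDL band while keeping the
14-tooth model around the element counts quoted above.

## Finite elements

Elements are 4-node constant-strain tetrahedra with three translational
degrees of freedom per node (the classical linear tet). Materials are
isotropic homogeneous linear elastic, in a consistent mm–N–MPa system:

| region | E (MPa) | ν |
|---|---|---|
| tooth | 20300 | 0.26 |
| PDL | 68.90 | 0.45 |
| splint (PMMA) | 2200 | 0.35 |

The element stiffness is $K_e = V B^\top D B$; assembly is fully vectorised
through the closed form $K_{ab,ij} = V(\lambda g_{a,i} g_{b,j} + \mu g_{a,j}
g_{b,i} + \mu\,\delta_{ij}\, g_a \cdot g_b)$ with the shape-function
gradients $g_a$. The reduced system is solved by sparse Cholesky
(CHOLMOD via the Matrix package), with a Jacobi-preconditioned
conjugate-gradient fallback (relative tolerance 1e-10); every solve checks
the relative residual against 1e-8 and recovers reactions at constrained
DOFs, so global equilibrium is verified per run rather than assumed.
Dirichlet conditions support per-node full fixation (the pipeline's use) and
per-component constraints (used by the verification benchmarks for symmetry
rollers and prescribed linear fields).

Stress is element-constant; reported maxima are maxima over element values
with **no nodal averaging**. This choice is stated explicitly because
averaging conventions change maxima: element-value maxima are systematically
sharper than averaged nodal fields, especially at load-application points
and re-entrant interface corners of the staircase surfaces.

### Verification

The test suite pins the solver to independent references: an element-level
oracle that derives the strain-displacement matrix from a shape-function
linear solve (a different route than the production cross-product form);
a dense brute-force assembly and `base::solve` path on small meshes
(agreement to 1e-9); the constant-strain patch test on an irregular patch
(1e-8); an axial bar against δ = FL/EA (1e-6, exact for this element);
monotone convergence of a cantilever tip deflection towards the
Euler–Bernoulli value under mesh refinement; and the von Mises closed forms
(uniaxial, hydrostatic, pure shear).

## Scenarios and post-processing

`build_scenario()` translates a measurement into a load case. The occlusal
force is a static force applied evenly over the nodes of the relevant
occlusal set — per tooth in option 1, on the splint top in options 2/3 —
with default direction −z (vertical). The direction is configurable
because the load can also be read as acting along the contraction vector of
the mandible-lifting muscles rather than along the tooth axis; the package
defaults to vertical and exposes the vector.

`summarize_solution()` reports per-region maxima; `compare_options()` forms
per-tooth ratios between options (zero denominators yield `NA`);
`safety_check()` compares maxima against the published thresholds —
physiological mobility 0.03 mm, the conservative dentin tensile bound
44.40 MPa (the low end of the published 44.40–97.80 MPa range; the choice
is configurable), per-class PDL limits (incisor 1.50, canine 1.60,
premolar 1.40, molar 1.20 MPa, the lower bounds of the published ranges),
and the PMMA minimum tensile fracture stress 32.00 MPa. Verdicts use strict
inequality: a value exactly at its threshold is reported unsafe with margin
1.0. Only the static PMMA check is implemented; fatigue-life estimation
would require material S-N curves that the package does not carry.

Because the synthetic teeth are miniaturised, full clinical loads
(~130–260 N) concentrate on small cross-sections and some dentin-stress
checks on the synthetic arch report unsafe — an expected property of the
reduced geometry, not a statement about any patient.

### The stress-location property

Without a splint each tooth is an independent cantilever-like body held by
its PDL. Under a load with a lateral (muscle-vector) component the tooth
bends, and the maximum von Mises element sits adjacent to the constrained
PDL interface at the root. The tests assert this qualitative property on a
toy dentition with direction `(0.3, 0, -1)/|.|`; under a purely vertical
load on the idealised axisymmetric tooth the bending mechanism vanishes
and local maxima at the discrete load-application nodes can compete, so the
oblique direction is the honest way to probe the mechanism.

## Numerical choices and degenerate inputs

* Cell classification is by centroid; a solid thinner than a cell can mesh
  empty, which is an error (`region ... is empty after meshing`).
* All generators are pure functions of (spec, seed); the only randomness is
  the phantom's HU noise, seeded and restored via the spec's `random_seed`.
* Duplicate Dirichlet specifications are deduplicated first-wins; a load on
  a fixed node is absorbed into the reaction.
* Unconstrained or rigid-motion-permitting systems fail with an explicit
  singularity error rather than returning garbage.
* 26-connectivity is used for segmentation components (the permissive 3-D
  standard); the labelling is cross-checked against a flood-fill oracle.

## Known limitations

* Mandibular bone is not modelled; the PDL outer surface is rigidly fixed.
  This overstiffens the support and shifts stress towards the root.
* The splint–crown bond is ideal (node-merged); no sliding, separation or
  frictional contact.
* Geometry is idealised and reduced-scale (see above): no crowding,
  inclination, wear facets or patient anatomy.
* Static linear analysis only: no material or geometric nonlinearity, no
  cyclic loading.
* Eccentric/lateral load cases and maxillary splints are out of scope.

## Problem sizes used by the checks

The bundled tests and the acceptance script run: toy dentitions of 1–3
teeth (a few thousand elements) for unit-level mechanics, the full
14-tooth arch (≈54k elements without splint, ≈97k with) once per design
option, verification bars of 480–7680 elements, and a ≈550k-voxel phantom.
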