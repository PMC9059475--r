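---
title: "Methods: multiscale bone phenotyping with osteomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale bone phenotyping with osteomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`osteomech` reimplements, as a tested pipeline, the computations behind a
multiscale skeletal phenotype comparison of wild-type (WT) and conditional
knockout (KO) mouse femurs: micro-CT trabecular/cortical morphometry,
cross-sectional flexural-rigidity profiling, AFM nanoindentation analysis,
three-point-bending metric extraction, voxel finite-element (FE) bending
simulation, and calcein histomorphometry. Because no raw scans or curves are
deposited for this kind of study, every analysis stage is exercised on
synthetic phantoms with analytic ground truth; this vignette records the
models, the numerical choices, and what the synthetic inputs do and do not
establish about real data.

## Synthetic phantoms

`make_femur_phantom()` builds a labeled voxel volume (0 background,
1 cortical, 2 trabecular, 3 marrow) on an isotropic grid (default 11.25 um,
within the 5.625-11.25 um range of desktop micro-CT of mouse femurs): a
closed cortical ring of constant wall thickness around a metaphyseal
trabecular compartment and a marrow-filled diaphysis. The growth-plate plane
is carried as an axial coordinate in metadata rather than as a label,
because segmenting a real growth plate is out of scope; every downstream VOI
rule only needs the coordinate.

The trabecular compartment is a *regular three-axis rod lattice with seeded
positional jitter*, not a stochastic Gaussian field. The regular lattice was
chosen because it has closed-form ground truth: rod diameter `t` is the
designed Tb.Th; the pore inscribed-sphere diameter `sqrt(2) * s - t` (rods
lie along cell edges, at perpendicular distance `s/sqrt(2)` from the cell
centre) is the designed Tb.Sp. The solid fraction of the lattice is
available in closed form by inclusion-exclusion (three rod families, minus
three pairwise crossings of perpendicular rods, `16 r^3 / 3` each, plus the
Steinmetz tricylinder core `8 (2 - sqrt 2) r^3`), and `make_femur_phantom`
inverts this expression for the pitch `s` so that the voxel-counted BV/TV in
the standard VOI hits the requested target. Jitter (8% of the pitch,
seeded) breaks the perfect periodicity so that cohort replicates are not
bit-identical; it is kept small enough that the nearest-lattice-cell
assignment used during voxelization stays exact.

`phantom_presets()` encodes the WT/KO study contrast: KO trabecular BV/TV
target 0.03 vs WT 0.12 (a 75% knockdown), KO struts 10% thicker and much
sparser, identical cortical wall (0.2 mm, cortical thickness is an
explicitly unaltered index), and a KO diaphyseal outer radius of 0.49 mm vs
WT 0.60 mm so the mid-shaft section is visibly reduced. Tissue moduli (GPa)
ride along as an attribute: WT cortical El/Et exceed KO by 43%/51% and
trabecular by 33%/25%, with WT El 10 GPa chosen as a plausible
nanoscale-indentation cortical value and every anisotropy ratio El/Et inside
the reported 1.2-2 (WT) and 1.3-1.5 (KO) ranges. A per-specimen outer-radius
scatter (3% CV, seeded) emulates biological size variation so that cohort
group statistics have honest within-group variance.

Curve generators follow the same pattern. `synth_indentation_curve()`
samples the Hertz spherical-contact law on a uniform depth grid (200 points
by default; AFM protocols do not fix a sampling density, and metric
recovery is grid-density invariant) with additive Gaussian force noise only
- the simplest model consistent with instrument noise. `synth_bending_curve()`
produces a quadratic toe (apparatus engagement), a linear elastic segment, a
post-yield hardening branch at 0.2x the elastic slope, a shallow post-peak
decline and a sharp fracture drop; the hardening fraction is the one
genuinely free shape parameter and 0.2 was fixed analytically so that the
0.2%-offset yield construction lands near the designed yield load on the
piecewise curve: with elastic slope `k` and post-yield slope `q k`, the
offset line crosses the hardening branch `offset * k * q / (1 - q)` above
the kink load, under 3% of yield at `q = 0.2`.
`synth_calcein_dataset()` draws per-field interlabel distances with mean
`MAR x 7 days` and splits the labeled surface 70/30 between double and
single labels.

What the phantoms do **not** emulate: realistic trabecular architecture
statistics (plate/rod mixtures, anisotropy, connectivity), CT reconstruction
artifacts, partial-volume gray levels (phantoms are pre-labeled;
segmentation of real scans is out of scope), cantilever calibration physics,
and post-yield micro-damage mechanics. Passing tests therefore establish
that the *computations* are correct on known geometry, not that the pipeline
segments or calibrates real scans.

## Micro-CT morphometry

The trabecular VOI follows the standard rule: a 2 mm axial region starting
1 mm below the growth plate, half-open in z, with TV taken as the
trabecular compartment (trabecular + marrow voxels) when marrow is labeled.

* **BV/TV** is voxel counting.
* **BS/TV** uses a triangulated isosurface. The surface is extracted by
  marching tetrahedra (Kuhn 6-tet decomposition, consistent across cells)
  from the *signed Euclidean distance field* of the phase, smoothed with a
  1-voxel Gaussian. The smoothing matters: discrete EDT level sets are
  boundaries of unions of balls around lattice points, and their scallops
  inflate triangulated areas by roughly 10%; smoothing removes the scallops
  while leaving planar boundaries exact (a digital sphere's area is then
  recovered to well under 1%). VOI boundary faces are left open (no end
  caps), matching scanner-software convention.
* **Tb.Th / Tb.Sp** use the model-independent maximal-inscribed-sphere
  definition, computed from the exact EDT by sphere painting with a
  half-voxel boundary offset: a centre with EDT radius `r` paints
  `2r - 0.5` voxels of thickness over the voxels its sphere covers, and
  redundant centres (spheres nested in a neighbour's) are pruned first.
  Plates and rods are recovered within half a voxel; Tb.Sp runs the same
  code on the intra-VOI background.
* **Tb.N** is the direct 3D convention `1 / (Tb.Th + Tb.Sp)`; scanner
  software packages use differing unreported formulas, so the
  model-independent default was adopted and is recorded here so an alternate (e.g. plate
  model) can be swapped in.
* **SMI** is `6 V S' / S^2` with `S'` a central difference of isosurface
  area under signed-distance offsets. Two numerical choices: the offset
  surfaces are taken from the smoothed distance field *renormalized by its
  local gradient magnitude* (smoothing averages divergent scallop gradients
  and would otherwise stretch the level spacing by ~10%), and the half-step
  is 1 voxel (the central difference is exact for the quadratic area growth
  of ideal shapes, so the larger step costs nothing in bias and halves the
  sensitivity to the residual half-voxel level-set error). Ideal plate,
  cylinder and sphere come out within 0.1 of 0, 3 and 4.
* **Ct.Th** is the local-thickness mean of the cortical label over a
  diaphyseal range (default: the distal quarter of the volume).

Undefined metrics (empty phase, zero surface) raise a typed condition
rather than returning 0, since 0 is a valid SMI/thickness value.
Connectivity conventions are 26 for foreground and 6 for background; all
internal lengths are mm, voxel indices 0-based, z intervals half-open.

## Section geometry

`section_properties()` treats each voxel as a filled square: its own
`a^4/12` plus the parallel-axis term, which removes the point-mass bias on
thin cortical walls. Principal moments come from the eigen-decomposition of
the 2x2 second-moment tensor; at exact ties (`Ixx = Iyy, Ixy = 0`) the
principal angle defaults to 0. `C1`/`C2` are measured from the principal
axes to the farthest foreground voxel centre, consistent with the
voxel-centre centroid convention; `Imax/C1` and `Imin/C2` are the geometric
bending coefficients reported along the shaft by `rigidity_profile()`,
which uses cortical + trabecular labels by default (the whole mineralized
section) and attaches `E * Imin` when a modulus is supplied. Which
coefficient corresponds to the anterior-posterior test axis is not
determinable from the study; both are always reported.

## Nanoindentation

The spherical-indenter Hertz relation is used in the form
`F = (4/3) E / (1 - nu^2) sqrt(R) delta^{3/2}`, i.e.
`E = 3 F (1 - nu^2) / (4 sqrt(R delta^3))`. The fit is *linearized* - least squares of `F` on
`delta^{3/2}` through the origin - rather than nonlinear optimization:
closed form, no initialization, and residuals stay in force units. The
origin constraint is a model requirement once the contact offset is
subtracted; `detect_contact_point()` finds the offset by a baseline
threshold (3 baseline SDs) refined by minimizing the origin-constrained fit
residual over offsets near the crossing. Depth is capped at 50 nm by
default - the infinitesimal-strain condition of the protocol - as a hard
filter. The Poisson ratio defaults to 0.3 (the value the FE section states
for bone) when curve metadata omits it; the value used for the original AFM
analysis is unstated. With nm/nN units the modulus comes out in GPa.
Frequency dependence is summarized by the empirical stiffening law
`E = a + b ln f` over 1-100 Hz via ordinary least squares.

## Three-point bending

The initial toe of a load-displacement record reflects apparatus compliance
and specimen engagement, not the bone, and is excluded: the elastic window
is the contiguous run of moving-window slopes at >= 80% of the running
maximum, ending before the force peak. Stiffness is the maximum
moving-window slope within that window, with the stiffness pass using a
window of half the elastic segment: the nominal 10%-of-window width makes
the max-over-windows estimator noise-dominated (slope SD scales as
n^{-3/2}), while the half-window estimator is identical on noise-free data
and unbiased to ~2% at the 0.1 N noise level of the recovery tests. Yield
uses the reproducible 0.2%-of-span offset construction - test reports
often give a "load at yield" without defining the rule - and the offset is
configurable.
Fracture is a force drop exceeding 50% of peak between consecutive samples;
work to fracture is the trapezoidal integral up to that point. The reported
"Young's modulus" of whole-bone records (N/m-scale slopes) is treated as a
whole-bone stiffness proxy, labeled `stiffness`, and never converted to a
tissue modulus without section geometry. The support span is ambiguous in
the protocol ("7 mm from each side"); span is therefore an explicit
parameter, default 7 mm, and stiffness is standardized on N/mm.

## Voxel finite elements

Each solid voxel becomes an 8-node trilinear hexahedron; since all elements
share one size, one 24x24 stiffness per material is cached and assembly is
a scatter of that kernel. Volumetric locking from near-incompressible
marrow (E = 20 MPa, nu = 0.499; bone nu = 0.3, isotropic - the standard
constitutive choices for whole-bone elastic models) is handled explicitly with B-bar (mean
dilatation) integration; a commercial solver does this implicitly. The
element-centre B matrix equals the element mean, so centre strain recovery
is B-bar consistent.

Three-point bending is modeled as simple supports: vertical displacement
fixed on two transverse bottom node lines at midspan +/- span/2, the load
(5 N by default, the protocol load) spread over the one-voxel-wide top node
line at midspan - a single-node point load would be singular - and rigid
modes removed by fixing the axial DOF on one support line plus one lateral
DOF at its central node. The system is solved by supernodal sparse Cholesky
(the simplicial default is an order of magnitude slower at these sizes);
meshes must be a single face-connected component, and floating voxels are
reported before the solver can fail. Von Mises stress uses the standard
deviatoric form; equivalent strain is `sqrt(2/3 e:e)` on the deviatoric
strain. Midspan deflection is the mean vertical displacement of the midspan
section (averaging out the local dimple under the load line).

Verification: on a hollow-tube phantom with slenderness 13.3 (outer
diameter 0.9 mm, span 12 mm, 60 um voxels, ~21k elements) midspan
deflection lands within 5% of `F L^3 / 48 E I` - the residual is mostly
genuine shear deflection, ~2.6% by Timoshenko's correction for a thin tube
- and outer-fiber von Mises stress within a few percent of `M c / I`
evaluated away from the load point (Saint-Venant). Reactions balance to
1e-6 relative; the solution is exactly linear in the load. The KO-vs-WT
field comparison uses annulus phantoms with the preset radii and moduli
because real femur geometries for such comparisons are typically not
deposited: only the
directions (higher KO von Mises stress and strain) and the scaling laws are
reproducible, not the reported 44%/75% magnitudes, which depend on specimen
anatomy.

## Histomorphometry and statistics

Histomorphometry operates on measurement tables, as the original
measurements were manual: `MAR = mean interlabel distance / 7 days`,
`MS/BS = (dL + sL/2)/BS`, `BFR/BS = MAR x MS/BS` (fixed to um^3/um^2/day,
the ASBMR unit convention; no obliquity correction is applied to interlabel
distances). Osteoclast densities apply
the three-or-more-nuclei counting rule before dividing by bone perimeter.

Group statistics use the classical pooled-variance unpaired two-tailed
t-test (Welch by flag) and one-way ANOVA, both delegated to the standard R
implementations; no multiple-testing correction is applied by default
(a Holm adjustment is available by flag). Expression analysis is delta-delta-Ct with
fold change `2^{-ddCt}`; RANKL/OPG-type indices are ratios of group means
with a seeded 2000-resample bootstrap CI. `build_report()` assembles
per-metric WT/KO means, SDs, n, percent differences and p-values with
provenance attached.

## Problem sizes and reproducibility

Default cohort runs use n = 5 femur phantoms per genotype at 11.25 um
voxels (about 13M voxels each), n = 7 bending curves per genotype, three
indentation curves per compartment/orientation/specimen, and the ~21k
element FE tube; a full WT/KO phenotype comparison completes in a few
minutes on one core. All randomness flows through explicit integer seeds -
one seeded generator per synthetic object - so any cohort is bit-identical
across runs. The command-line front end (`inst/cli/osteomech`) is a thin
wrapper over the same functions.

## Known limitations

* Morphometry conventions (Tb.N formula, SMI step, surface smoothing) are
  one defensible choice among several scanner conventions; absolute values
  can differ from a specific vendor's software even when directions agree.
* The local-thickness painting is exact only up to the half-voxel boundary
  offset; sub-voxel structures are not resolved (struts must be at least 2
  voxels across, which the phantom parameters enforce).
* The FE model is small-strain, isotropic, linear; it answers the elastic
  bending question only, and support/load lines are rigid constraints
  rather than contact.
* Yield by the offset rule on a piecewise-linear synthetic curve is
  systematically a few percent above the designed kink load; the recovery
  tolerance (5%) accounts for this.
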