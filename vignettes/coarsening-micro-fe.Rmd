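---
title: "Voxel coarsening and micro-FE of trabecular bone: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel coarsening and micro-FE of trabecular bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MicroCT can image trabecular bone at ~36 µm resolution, fine enough to build
voxel-based finite-element (micro-FE) models whose apparent elastic modulus
tracks the mechanical competence of the specimen. Clinical imaging cannot:
in vivo modalities deliver 100–300 µm voxels and far fewer slices. `trabfe`
implements the machinery to study what is lost on the way down: it degrades
a full-resolution binary slice stack by four controlled coarsening schemes,
converts each degraded model to a hexahedral FE mesh, solves linear-elastic
uniaxial compression, and regresses the decay of the apparent modulus
against the classical structural indices of the specimen.

## Model construction

**Basic model.** N binary slices (1 = bone), 36 µm pixels, 36 µm apart, give
N−1 layers of cubic voxels. A voxel is bone exactly when the pixel at its
(i, j) position is bone in *both* bounding slices (the AND rule). The AND
reading of the construction rule also governs all slice-pairing schemes
below; it is conservative — a voxel exists only where bone is present at
both of its faces.

**Hexahedral (H).** The basic model's grid is tiled by s×s×s cuberrilles
(s a multiple of 36 µm, conventionally 72–288 µm) anchored at the origin. A
cuberrille becomes one bone voxel of edge s when strictly more than 50 % of
its *nominal* volume is bone — partial cuberrilles at the boundary keep the
full nominal denominator, so under-filled edge cells tend to empty. This is
the only scheme that degrades in-plane resolution.

**First-Last (F-L).** Layer k (thickness d, a multiple of 36 µm) is the AND
of the slices at its bottom and top faces, k·m and (k+1)·m with
m = d/36 µm. Trailing slices that do not complete a layer are dropped, so
the model never exceeds the source extent.

**First-Second (F-S).** Layer k is the AND of the two *successive* slices
k·m and k·m+1, extruded to thickness d. Only two closely spaced slices per
layer are needed — the dose-reduction motivation of the scheme.

**First-Third (F-T).** As F-S but the pair is 72 µm apart (k·m and k·m+2),
so d must be a multiple of 72 µm. At d = 72 µm F-T and F-L coincide by
construction, which the tests assert on arbitrary stacks.

Layer anchoring at k·m from slice zero keeps the layers a non-overlapping
tiling of the specimen height; the alternative (padding a trailing partial
layer) would fabricate data and is not done.

## Finite elements

Each cubic voxel maps to one 8-node trilinear hexahedron; an elongated
36×36×d voxel maps to d/36 stacked cubic elements. Nodes are merged exactly
via integer lattice addressing. All elements are identical cubes, so one
24×24 stiffness matrix (2×2×2 Gauss quadrature, exact for the undistorted
trilinear element) serves the whole mesh. Tissue properties default to
E = 10 GPa, ν = 0.3 — the convention for human trabecular tissue in
voxel-based micro-FE.

Elements connected to the rest of the structure only through shared edges
or corners transmit no stiffness through conforming hexahedra and make the
system singular; `filter_connectivity()` therefore keeps exactly the
largest face-connected component (ties broken toward the lowest element
index). Components not touching both loading faces are *not* additionally
removed; they simply carry no load.

**Boundary conditions.** The bottom face gets zero axial displacement, the
top face −ε·H with ε = 0.8 % by default; lateral displacements on both
faces are free (frictionless platens), which is what makes the solid-block
and prism patch tests exact. Three lateral rigid-body modes remain and are
pinned minimally: one bottom-face node is fixed in x and y, and a second
bottom-face node sharing its y-coordinate is fixed in y. Because the
uniform-strain solution has zero lateral displacement along that shared-y
line (up to a rigid motion), the pins do not perturb the stress state; the
translation-invariance and patch tests verify this to machine precision.

The assembled system is solved with a supernodal sparse Cholesky
factorisation (CHOLMOD via the Matrix package); a Jacobi-preconditioned
conjugate-gradient solver (`solver = "cg"`, relative residual 1e-8) is
available as an alternative contract for larger systems. The compressive
axial force F is the sum of axial reactions on the driven face, checked
against the fixed face for equilibrium, and the apparent modulus is
E_app = (F / A_nominal) / ε with A_nominal the *specimen* cross-section
(mask area when a cylindrical mask is present, bounding box otherwise) —
never the bone area.

## Morphometry

* **BV/TV** — bone voxel count over the examined volume (masked volume when
  a mask exists).
* **Tb.Th** — local thickness: the mean over bone voxels of the diameter of
  the largest inscribed sphere covering each voxel. Sphere centres live on
  a half-voxel-pitch lattice (voxel centres, face centres, edge midpoints,
  corners); a centre's radius is its Euclidean distance to the nearest
  non-bone lattice node minus one fine pitch, placing the bone surface
  halfway between bone and background samples. On an extended slab of t
  voxels this evaluates *exactly* to t·36 µm, and an isolated voxel gets
  36 µm — the two closed forms a voxel-centre-only definition cannot
  satisfy simultaneously. Space beyond the grid counts as marrow by
  default; `boundary = "solid"` (per axis) suppresses edge effects on
  periodic fixtures.
* **Tb.N** — the plate-model ratio (BV/TV)/Tb.Th, so Tb.N·Tb.Th = BV/TV
  holds identically.
* **Vm** — mean bone volume per model layer, in mm³.

Cohort summaries report min, max, mean, sample SD and the relative standard
deviation as 100·SD/mean (percent).

## Phantoms

No public scans exist for the kind of specimen this pipeline targets, so
the package generates its own study material.

Deterministic fixtures carry closed-form answers: the solid block
(E_app = E_tissue for every coarsening, since all four schemes are the
identity on solids), the prism column occupying an exact area fraction φ
(E_app = φ·E_tissue under frictionless compression), and the parallel-plate
lattice (BV/TV = t/p, Tb.Th = t·36 µm, Tb.N = (BV/TV)/Tb.Th).

The stochastic phantom thresholds a smoothed Gaussian random field (GRF) at
the empirical quantile of the target volume fraction, which pins realized
BV/TV to the target within one voxel count. Its parameters:

* `correlation_length` (default 100 µm): the Gaussian smoothing length, the
  trabecular thickness/spacing analogue. At volume fractions near 0.22 it
  yields Tb.Th ≈ 0.15 mm, the middle of the range observed in femoral-head
  cores (0.089–0.259 mm).
* `anisotropy` and `oriented_fraction`: by default the field is isotropic.
  Setting `anisotropy > 1` mixes in an axially elongated covariance
  component (amplitude weight `oriented_fraction`), emulating the femoral
  head's oriented primary compressive trabeculae on top of an isotropic
  secondary network.

The isotropic default was kept deliberately after studying the
alternatives. An isotropic excursion set at BV/TV ≈ 0.2 sits near its
percolation threshold on desk-scale domains: the basic model is soft (tens
of MPa) and some realizations have no spanning load path at all. Cohort
studies therefore **screen realizations for a nonzero basic-model reaction
force** — the in-silico analogue of the fact that every physical specimen
necessarily carries load — and work with relative moduli, which are
scale-free. The tempting alternative, elongating the field axially until
the load path is robust, turns the trabeculae into straight columns; those
survive cuberrille majority voting and slice-pair extrusion almost
untouched, so the H and F-S decays that motivate the whole analysis
disappear (and H can even stiffen, as majority voting fattens a straight
column into full cuberrilles). Obliqueness is the very property the
coarsening schemes punish; removing it to gain numerical comfort would
answer a different question.

What the GRF phantom does **not** emulate: plate-rod duality, branching,
cortical shells, marrow-space gradients, and — critically — the combination
of *redundant connectivity* with *tortuosity* that real trabecular networks
achieve at physiological volume fractions but a near-percolation random
field cannot. On such marginal networks, stiffness under coarsening tracks
the fragility of the percolation backbone rather than the bone-volume
budget: the Hexahedral method severs the backbone essentially at its first
coarsening step, and First-Second (whose consecutive layers share no
source slice) loses vertical connectivity about as fast as First-Last
loses density. What the cohort tests consequently do and do not show: the
decay is negative for every method, the slice-pairing pair is collectively
gentler than the H/F-L pair, and F-S and F-T are indistinguishable within
seed-to-seed spread — but the finer pairwise distinction between F-L and
F-S is lost in that spread, the decay magnitudes are not those of patient
specimens, and no load-bearing realization exists at all below the
excursion-set percolation threshold (bone fraction ≈ 0.16), so
very-low-density cohorts cannot be studied with this generator.

## Analysis

`relative_modulus_curve()` normalises each coarsened modulus by the basic
model's; the basic model itself is the curve's first point (RE = 1 at the
native 36 µm voxel length, definitionally), so a model that collapses at
its first coarsening step still shows its decay rather than a flat
all-zero curve. A coarsened model with no load-bearing structure left (no
bone, or no component spanning the platens) enters the curve as RE = 0.
Two fit forms are provided because
both appear in practice: a straight line in d, and `log_fit()`,
RE = a·ln(d) + b over points with d ≤ 300 µm (the range where the
logarithmic description of the decay holds). `slope_index_table()`
regresses per-sample |a| on each structural index per method; porous
specimens decay faster, so those regression slopes come out negative. R²
of a zero-variance response is defined as 0.

## Problem sizes and numerical choices

Cohort experiments in the test-suite run at 40×40×64 voxels
(1.44×1.44×2.3 mm) with five seeds at BV/TV 0.22 and three seeds per cohort
for the 0.10/0.35 comparison; d-grids are H {72,108,144} µm (coarser
cuberrilles would leave under ten cells across this section) and
{72,108,144,216,288} µm for the slice-pairing schemes ({72,144,216,288} for
F-T). These sizes are the package's choice of desk-scale defaults; the
machinery itself is size-agnostic.

Other conventions: binarization is grey ≥ threshold; cylinder-mask
membership is pixel-centre-in-disc; parameter ranges (s ∈ [72, 288] µm,
d ∈ [72, 1080] µm) are enforced with an `enforce_range = FALSE` override
since they are experimental conventions, not algorithmic necessities;
direct solves are exact to machine precision and the CG tolerance defaults
to 1e-8 relative.

## Known limitations

Linear elasticity only — no yield, damage or geometric nonlinearity; no
heterogeneous tissue modulus from mineralization; no friction-platen
boundary option; Tb.Th/Tb.N are the plate-model/local-thickness variants
only (no MIL anisotropy, SMI or connectivity density); the GRF phantom
limitations above. The pure-R distance transform and sphere painting make
morphometry the slowest step on large grids; the FE path is sparse-direct
and memory-bound near ~10⁵ elements.
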