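---
title: "Modelling bone-cement infiltration and its mechanical effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bone-cement infiltration and its mechanical effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Prophylactic femoroplasty injects PMMA bone cement into osteoporotic
trabecular bone to raise its fracture resistance. Planning such an
augmentation requires predicting (i) where a given volume of cement of a
given viscosity will spread when pushed into a porous structure along a
chosen direction, and (ii) how much the resulting bone–cement composite
stiffens. `voxcem` implements a desk-scale simulation chain for both
questions on labelled voxel grids (void / bone / cement): a discrete
particle model of infiltration, a voxel finite-element compression
analysis, geometric scoring of the cement cloud, and a factorial study
pipeline over structure porosity, cement viscosity and injection
direction.

```{r setup, eval = FALSE}
library(voxcem)
```

## The discrete particle model of infiltration

Cement is represented as a stream of particles, each occupying one voxel
once settled, so that the injected volume maps to a particle count through
the voxel volume: `N = floor(V * 1000 / h^3)` with `V` in ml and the voxel
edge `h` in mm. At the reference resolution of 0.16 mm, 4 ml corresponds
to 976,562 particles.

Each particle performs a biased random walk on the 26-voxel Moore
neighbourhood. The 26 offsets are partitioned into four probability
classes; the class probabilities follow from a ratio chain and the
normalization `sum(n_i * p_i) = 1`, solved in exact integer arithmetic:

* **vertical** injection (preferred offset `(0, 0, +1)`): ratios
  `p1 = 15 p2 = 50 p3 = 90 p4`, class sizes `(1, 8, 8, 9)` — the on-axis
  forward offset, the remaining forward-layer offsets, the lateral layer,
  and the backward layer. This gives `p1 = 150/269`, and a free-space mean
  drift of `215/269 ≈ 0.8` voxels per step along the injection axis.
* **diagonal** injection (preferred offset `(+1, 0, +1)`): ratios
  `p1 = 5 p2 = 20 p3 = 90 p4`, class sizes `(1, 2, 4, 19)`, giving
  `p1 = 90/163`.

The diagonal class sizes `(1, 2, 4, 19)` are the unique integer partition
with a single most-preferred offset that reproduces the printed
normalization exactly; the *geometric membership* of classes 2–4 is less
constrained, and the package assigns class 2 to the two body diagonals
adjacent to the preferred offset and class 3 to the four offsets next
closest in angle (ties broken lexicographically). This assignment is a
documented convention, not a derived fact.

Interaction rules:

* **Bone exclusion and contact inhibition.** Offsets whose immediate
  neighbour voxel is outside the grid or not VOID are excluded from the
  draw and the remaining weights renormalized; settled cement blocks
  subsequent particles just as bone does. A particle never remains in
  place while any offset is admissible; a fully enclosed particle stops
  walking ("jammed") and proceeds to settlement.
* **Viscosity as jump size.** After drawing an offset the particle
  advances up to `jump_size` voxels along it, truncating before the first
  non-VOID voxel (no tunnelling). High-viscosity cement uses jump 1,
  low-viscosity jump 5 — a phenomenological encoding of the higher shear
  rate of a less viscous cement at equal shear stress.
* **Settlement.** After its walk the particle settles at its position if
  VOID, otherwise at a vacancy drawn uniformly from the 26-neighbourhood,
  then from Chebyshev shells of growing radius up to `settle_radius`
  (default 3); beyond that it is counted as *blocked*. Blocked particles
  are reported in the mass balance, never silently retried.
* **Walk length.** How long a particle walks before settling is a free
  parameter of this model class; `max_steps_per_particle` (default 200)
  makes it explicit and bounds runtime. With drift ≈ 0.8 voxels/step the
  default comfortably spans desk-scale domains (64–128 voxels).

Particles are released sequentially from the entry voxel (the "drilled"
access point, by default the void voxel nearest the bottom-face centre).
Determinism is guaranteed given a seed: the walk uses R's seeded RNG, and
the study pipeline derives per-run seeds from the base seed and factor
indices with an integer congruential hash.

## Synthetic open-cell structures

The in-silico study needs porous substrates with controlled porosity.
`generate_open_cell()` builds them from smoothed Gaussian noise,
thresholded at the *exact sample quantile* of the target porosity, so the
achieved void fraction is correct to within one voxel by construction.
Two field constructions are available:

* `method = "struts"` (default): the solid phase is
  `max(|f1|, |f2|) < t` for two independent smoothed fields — a thin
  neighbourhood of the intersection curves of their zero surfaces. This
  produces a rod-like, almost fully connected strut network, the defining
  topology of open-cell foam: at 85% porosity ≈ 98% of the solid sits in
  one face-connected component, and apparent moduli come out at the tens
  of MPa, the right scale for trabecular surrogates.
* `method = "blobs"`: a single thresholded field. Simpler, but at 85%
  porosity the 15% solid phase sits near the percolation threshold of
  level-set excursions: most of it fails to span the domain and the
  remnant is floppy (apparent modulus ~1 MPa). It is kept for contrast
  and for tests.

The generator enforces an open void phase: the largest 26-connected void
component must span the injection axis, else the field is redrawn with an
incremented seed (bounded retries). `wall_thickness` adds BONE padding on
the four lateral faces, mirroring a rigid confining shell: impenetrable to
particles and rigidly bonded in the FE model. Porosity is matched before
padding and reported for the interior.

The generator emulates *porosity and interconnectedness only*. It does not
reproduce strut thickness distributions, anisotropy, or the mechanical
calibration of any particular foam product; passing trend tests on these
structures shows the simulation chain behaves correctly on open-cell
topologies, not that it predicts a specific specimen's numbers.

## Voxel finite-element compression

Every solid voxel (bone or cement) becomes a trilinear 8-node hexahedron
with full `2 x 2 x 2` Gauss integration; one unit stiffness matrix is
computed per Poisson ratio and scaled by `E * h` per element. Both phases
are linear elastic and isotropic — bone 3200 MPa, cement 2000 MPa,
`nu = 0.3` by default. A compressive strain (default 2%) is prescribed on
the top face along the k axis and the apparent Young's modulus is the
reaction force on the prescribed face over the *full* bounding
cross-section (voids included) divided by the strain — the specimen-level
(apparent) convention.

Two boundary-condition idealizations of the compression test are
provided. `bc_mode = "paper"` clamps the bottom face completely and
prescribes only the axial displacement on the top face (platen friction
idealized as perfect stick). `bc_mode = "frictionless"` constrains both
faces axially with minimal in-plane rigid-body pins; it recovers the
homogeneous uniaxial stress state exactly, which makes it the right mode
for verification oracles (a homogeneous block must return its material
modulus to machine accuracy; at `nu = 0` stacked and side-by-side
two-phase fixtures must hit the Reuss and Voigt closed forms). For
slender homogeneous blocks the two modes agree within 2%, the clamped
end effect being localized.

Only solid material on a face-connected (6-connectivity) load path from
bottom to top carries elements. Material attached solely through edges or
corners forms zero-energy hinges — the discrete system would be singular —
so it is excluded and reported (`n_excluded_elements`); if *no* component
spans the axis, the solver raises an error naming the largest component.
A useful corollary: flipping any void voxel to cement can only add
positive-semidefinite stiffness, so the apparent modulus is monotone
non-decreasing in cement placement (tested exhaustively on small grids).

Small systems (≤ 30k free DOFs by default) are solved with a sparse
Cholesky factorization. Larger systems use conjugate gradients
preconditioned by a geometric multigrid V-cycle, the standard approach
for voxel micro-FE: levels coarsen the voxel lattice 2:1 with
child-averaged Young's moduli (rediscretized coarse operators), smoothing
is a degree-2 Chebyshev polynomial on the diagonally scaled operator
(upper quarter of the spectrum, `lambda_max` from a short power
iteration), and the coarsest level (≤ 9k free DOFs) is factored directly.
Coarse levels clamp the bottom plane fully — identical to the paper mode,
and for the frictionless mode a preconditioner-only stiffening that keeps
every level SPD. The convergence criterion is the relative residual
against the *cold-start* Dirichlet residual, so an initial guess cannot
silently weaken it; the default guess is the linear compression ramp,
which is exact for homogeneous blocks. Measured on 64^3 strut structures,
MG-CG converges in roughly 20–60 iterations where diagonal-preconditioned
CG needs several thousand.

Tolerances: `solver_tol = 1e-8` by default. Study sweeps use `1e-4`
(the `study_config()` default), which reproduces tightly converged
apparent moduli to ~0.2% or better on 64^3 structures — two orders of
magnitude below the effects the study measures; `1e-3` was tested and
rejected (errors up to 15% on augmented solves).

## Cement-cloud metrics

`extract_cloud()` labels the cement phase under 26-connectivity with a
deterministic ordering (size, then first voxel). `cloud_metrics()`
reports voxel count, volume, surface area, Wadell sphericity
`psi = pi^(1/3) (6V)^(2/3) / A`, component count, centroid and radius of
gyration.

Two surface-area estimators are provided, and the choice matters:

* `"faces"` counts exposed voxel faces. It is exact for axis-aligned
  polyhedra (the cube closed form `psi = (pi/6)^(1/3)` to machine
  precision) and well-defined for any mask, but overestimates curved
  surfaces by up to ~1.5x, biasing psi low for sphere-like bodies.
* `"mesh"` triangulates the 0.5 level set of the mask after Gaussian
  smoothing (sigma = 1 voxel) with marching tetrahedra — table-free (the
  four tetrahedron cases are enumerated directly) and accurate for
  compact shapes: a digital ball of radius 16 yields psi = 1.004.
  Without smoothing the mid-point faceting overestimates the sphere
  surface by 28%; with it, structure thinner than the smoothing scale
  falls below the 0.5 level and loses its surface entirely.

That failure mode decides the defaults. Desk-scale injected clouds are
partly filament- and scatter-like, so the mesh estimator can report
near-zero area (unbounded psi) for them; `cloud_metrics()` therefore
defaults to `"faces"`, while the standalone `sphericity()` keeps `"mesh"`
for compact masks. Because the absolute sphericity of a voxel cloud is
estimator-dependent, only *comparisons under one estimator* (e.g. high-
versus low-viscosity cement on the same structure) are treated as
meaningful; multi-component clouds are scored on their union, with
per-component values also reported.

## The study pipeline

`run_study()` reproduces the factorial design: structures at porosities
0.85 / 0.79 / 0.69 x viscosity {high, low} x direction {vertical,
diagonal} x replicates. Per structure it generates the grid, solves the
unaugmented baseline, then per cell injects, re-solves, and scores the
cloud; per-run failures are recorded in an `error` column without
aborting the sweep. `summarize_study()` reports condition-level means
with both the sample standard deviation (n − 1) and the half-range
`(max − min)/2` — with two replicates a "mean (spread)" table can be
read either way, so both are emitted.

Defaults and their reasoning:

* **Domain 64^3 at 0.16 mm** (≈ 10 mm cube): large enough for ~20
  strut spacings at the default correlation length of 3 voxels, small
  enough that a full 120-run study (10 replicates) completes in minutes
  per condition on one CPU. The full-size specimen geometry
  (65 x 65 x 40 mm ≈ 406 x 406 x 250 voxels) is supported but is not the
  desk default.
* **Injected volume "auto"**: the same *fraction of the domain* as 4 ml
  occupies in a 65 x 65 x 40 mm specimen (≈ 2.37%), keeping the relative
  dose of the full-size scenario at any domain size. An explicit
  `V_cement_ml` overrides it.
* **`bc_mode = "paper"`** for study replication; frictionless remains the
  verification mode.
* **Seeds**: one structure per porosity (specimens are fixed objects;
  replication varies the injection), per-run seeds hashed from
  `base_seed` and the factor indices, so any single run can be
  reproduced in isolation.

On these synthetic structures the pipeline reproduces the expected
qualitative behaviour — every condition's mean stiffness improvement is
positive, and high-viscosity cement yields more compact (higher-psi)
clouds than low-viscosity cement on the same structure. Quantitative
values (improvements of a specific foam specimen, absolute sphericities)
depend on microstructure the generator does not emulate and on the
surface estimator, and are outside what these defaults claim.

## Known limitations

* The walk model is phenomenological: no pressure, flow rate, curing,
  rheology beyond the jump-size abstraction, and no bone-marrow
  interaction.
* Particle positions are voxel-quantized; one particle = one voxel couples
  the mass balance to the grid resolution, and a change of voxel size
  implies re-tuning the jump size.
* The FE analysis is linear elastic with perfectly bonded interfaces — no
  damage, yield, or fracture-load prediction.
* The generator matches porosity and open-cell connectivity only.
* Absolute sphericity values are estimator-dependent; only orderings are
  portable.

## I/O and interfaces

Grids read/write as MetaImage (`.mhd`/`.raw`, `MET_UCHAR`, spacing in
`ElementSpacing`), multi-page TIFF stacks (one page per k-slice; supply
the voxel size on read), or the native serialized container (`.rds`).
Labels are fixed at VOID = 0, BONE = 1, CEMENT = 2 in every format, and
out-of-range stored values are an error, never remapped. A thin
command-line front end (`inst/cli/voxcem.R`) exposes `grid`, `generate`,
`infiltrate`, `fem`, `metrics` and `pipeline` subcommands over these
functions for shell use.
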