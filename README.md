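# voxcem

Simulation of bone-cement augmentation in voxelized open-cell structures:
a discrete particle (biased random-walk) model of cement infiltration, a
voxel micro-finite-element compression analysis, and geometric scoring of
the injected cement cloud. The package targets computational biomechanics
workflows around prophylactic femoroplasty, where one wants to know how a
volume of PMMA cement of a given viscosity spreads into trabecular-like
porous structures along a chosen injection direction, and how much the
augmented structure stiffens.

## The model in brief

**Infiltration.** Cement is a stream of discrete particles on a labelled
voxel grid (VOID = 0, BONE = 1, CEMENT = 2); each settled particle fills
one voxel, so an injected volume V maps to `N = floor(V·1000 / h³)`
particles at voxel size h (mm). Particles walk on the 26-voxel Moore
neighbourhood with anisotropic class probabilities solved exactly from a
ratio chain under `Σ nᵢ pᵢ = 1`:

- vertical: `p₁ = 15 p₂ = 50 p₃ = 90 p₄`, class sizes (1, 8, 8, 9)
  → `p₁ = 150/269`; mean free-space drift 215/269 voxels/step;
- diagonal: `p₁ = 5 p₂ = 20 p₃ = 90 p₄`, class sizes (1, 2, 4, 19)
  → `p₁ = 90/163`.

Viscosity enters as the per-iteration jump size (high → 1 voxel, low → 5);
bone is impenetrable, settled cement obstructs later particles ("contact
inhibition"), and blocked particles are reported in the mass balance.

**Mechanics.** Solid voxels become trilinear hexahedral finite elements
(bone 3200 MPa, cement 2000 MPa, ν = 0.3, linear elastic); a 2% uniaxial
compressive strain yields the apparent Young's modulus
`E_app = (F / A_total) / ε` and the augmentation outcome
`improvement = 100·(E_aug − E_base)/E_base`. Large systems are solved by
conjugate gradients with a geometric multigrid preconditioner.

**Cloud metrics.** Connected components (26-connectivity), volume,
surface area (exact face counting, or a marching-tetrahedra isosurface for
compact shapes), Wadell sphericity `Ψ = π^{1/3}(6V)^{2/3}/A`, centroid and
radius of gyration.

## Worked example

```r
library(voxcem)

# a 64³ open-cell structure at 85% porosity, 0.16 mm voxels
g <- generate_open_cell(structure_spec(c(64, 64, 64), 0.85, seed = 11))
porosity(g)
#> [1] 0.8499985

base <- fe_solve(g, fe_config(solver_tol = 1e-4))
base$apparent_modulus
#> [1] 17.66758

# inject low-viscosity cement vertically (~2.4% of the domain volume)
cfg <- injection_config(V_cement_ml = 0.0254, viscosity = "low",
                        direction = "vertical", entry = find_entry(g),
                        seed = 5)
inj <- run_injection(g, cfg)
inj$result
#> <injection_result> low viscosity (jump 5), vertical direction
#>   requested 6,201, settled 6,201, blocked 0 (0.0254 ml of 0.0254 ml placed)

aug <- fe_solve(inj$grid, fe_config(solver_tol = 1e-4))
improvement(aug$apparent_modulus, base$apparent_modulus)
#> [1] 12.11867

glance(cloud_metrics(inj$grid))
#> # A tibble: 1 × 6
#>   n_voxels volume surface_area sphericity n_components radius_of_gyration
#>      <int>  <dbl>        <dbl>      <dbl>        <int>              <dbl>
#> 1     6201   25.4         608.     0.0687          275               4.24
```

Reading: the cement (6201 particles, all placed) stiffens this structure
by about 12%; the low-viscosity cloud is spread out (many satellite
components, low sphericity). The same chain with `viscosity = "high"`
produces a denser, rounder cloud (fewer components, higher Ψ).

The full factorial study — porosities 0.85/0.79/0.69 × viscosity ×
direction × replicates, with per-condition mean ± spread tables — runs
with:

```r
res <- run_study(study_config(replicates = 10, base_seed = 1))
summarize_study(res)
autoplot(res)                      # improvement by condition
autoplot(res, type = "sphericity")
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "voxcem.R", package = "voxcem")` with subcommands
`grid`, `generate`, `infiltrate`, `fem`, `metrics` and `pipeline`.

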