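---
title: "Mechanobiology-driven porosity optimization of graded bone scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanobiology-driven porosity optimization of graded bone scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgsopt)
```

## The design problem

Functionally graded scaffolds (FGS) are porous implants whose porosity
varies in space. Dense regions carry load; porous regions host cells and
nascent tissue. `fgsopt` asks: given the mechanical environment of a
scaffold — its material stiffness and the loads it must bear — what porosity
*gradient* lets the most bone form in its pores?

The package answers this with a mechanobiological pipeline:

1. **Parametric geometry.** A prismatic scaffold (square base `t = 2548` µm,
   height `h = 3822` µm) carries circular pores on a regular lattice. The
   pore radius `A(y)` varies only with the height coordinate `y` (`y = 0` at
   the loaded face, `y = h` at the clamped face) according to a
   piecewise-linear *porosity law*: constant, linear, bi-linear or
   tri-linear, with 1–4 coefficients `A_i ∈ [5, 300]` µm giving the radii at
   the law's breakpoints.
2. **Poroelastic finite elements.** The scaffold solid and the granulation
   tissue filling its pores are biphasic poroelastic continua. A load —
   compressive traction (1 MPa), shear traction (0.5 MPa), or their sum —
   is ramped over 1 s onto a rigid plate tied to the loaded face, and the
   coupled displacement–pressure problem is solved implicitly in time.
3. **Mechano-regulation.** For every pore-filling element the biophysical
   stimulus is `S = γ/a + v/b`, with `γ` the octahedral shear strain,
   `γ = (2/3)·sqrt((ε_I−ε_II)² + (ε_II−ε_III)² + (ε_III−ε_I)²)`,
   `v` the interstitial fluid flow (µm/s), `a = 0.0375` and `b = 3` µm/s.
   The stimulus selects a tissue phenotype: resorption (`S < 0.01`), mature
   bone (`0.01 < S < 0.53`), immature bone (`0.53 < S < 1`), cartilage
   (`1 < S < 3`) or fibrous tissue (`S > 3`).
4. **Objective.** The bone occupancy `BO% = 100 · V_BONE / V_TOT` sums the
   measure of mature-bone elements over the *full* prism measure
   `V_TOT = t × t × h` (24.814 mm³ in 3D). The optimizer minimizes
   `Ω = −BO%` over the law coefficients with a bound-constrained SQP
   iteration, and a factorial study driver crosses scaffold Young's moduli
   {500, 1000, 1500} MPa × loads {compression, shear, mixed} × the four law
   kinds — 36 optimizations.

Two summary metrics compare designs: `PVPD = 100·(A_H − A_L)/A_L`, the
percent variation of the pore dimension along the height, and
`iBO% = BO%_trilinear − BO%_constant`, the payoff of grading over a
homogeneous scaffold.

## Materials and their derived constants

Granulation tissue: `E = 0.2` MPa, `ν = 0.167`, permeability
`k = 1e-14` m⁴/(N·s), porosity 0.8, grain and fluid bulk moduli 2300 MPa.
The scaffold solid exposes its Young's modulus as a study factor; its other
poroelastic constants are not design variables and default to `ν = 0.3`,
`k = 1e-14` m⁴/(N·s), porosity 0.5 and the same bulk moduli, following the
established biphasic scaffold models this line of work builds on. From
`(E, ν, K_grain, K_fluid, n)` the solver derives the Biot coefficient
`α = 1 − K_drained/K_grain` and storage modulus
`1/M = (α − n)/K_grain + n/K_fluid`; for the granulation defaults
`α ≈ 0.99996` and `M ≈ 2300` MPa, i.e. nearly incompressible constituents.

```{r materials}
granulation_properties()[c("alpha", "M_Pa")]
```

## Numerical choices

**Kinematics.** Small-strain linear poroelasticity. All listed materials
are linear and the working strains are of order 10⁻³, so geometric
nonlinearity would change results at the 0.1 % level while substantially
complicating the solve.

**Discretization.** Linear displacement–pressure simplex elements
(triangles in plane strain, tetrahedra in 3D) on a structured grid, with
lumped storage and implicit backward-Euler time stepping (10 equal steps
across the 1 s ramp by default; the stimulus is evaluated at the end of the
ramp). Equal-order u–p elements are stable here because the evaluation
times are late enough that the sharp early-time pressure boundary layer has
left the domain; the Terzaghi benchmark below quantifies the accuracy. The
stiffness (~`E/L²`) and storage (~`vol/M`) blocks differ by ~25 orders of
magnitude, so the coupled matrix is symmetrically equilibrated before its
sparse LU factorization; the factorization is reused across equal time
steps.

**Pore realization.** No conforming mesher for multiply-connected domains
is available to the package, so pores are realized on the structured grid
by labelling each element *granulation* when its centroid falls inside a
pore disc and *scaffold* otherwise. The total mesh measure equals the
domain measure exactly, and the granulation measure converges to the
analytic disc area as the element size shrinks (first order). The lattice
is 5 rows × 3 columns at the cell centres of an even subdivision — the
reference geometry renders its pore layout only graphically, so the counts
are configurable; the defaults leave > 80 µm walls at the maximum
admissible radius. The radius of every pore in a row is the law evaluated
at the row's centre height.

**Rigid-plate tie.** The loaded-face nodes move rigidly with the plate. The
plate's rotation about its centroid is left free by default
(`plate_rotation = TRUE`): only the force resultant is imposed, no moment,
which is how a rigid-body tie loaded at its reference point behaves. This
matters for pure shear: with rotation suppressed the problem becomes a
fixed–fixed shear wall whose strain field is symmetric in height, whereas
the free-rotation plate produces the cantilever-like strain growth toward
the clamped face that drives the load-dependent gradation results.

**Drainage in the 2D reduction.** The model fixes `p = 0` on the *outer
granulation surfaces* — in the extruded geometry these are the channel
openings on the front and back faces. A mid-depth plane-strain section has
no such surface: at a 1 s ramp the channels have no time to drain through
their ends (the consolidation time of a 300 µm pore is tens of seconds), so
the faithful 2D default is an empty drained set (in-plane undrained).
`drainage = "pore_wall"` instead fixes `p = 0` on the pore rims, the fully
drained limiting case; with it the fluid contribution to `S` nearly
vanishes at desk meshes. The `coarse_3d` mode drains the channel ends
properly.

**Interstitial fluid flow.** `v` is the Darcy flux magnitude `‖−k∇p‖`
(µm/s) at the element centroid; `intrinsic = TRUE` divides by the porosity
for the pore-fluid velocity. The flow constant `b = 3` µm/s is commonly
stated against the flux, which is the default here.

**Stimulus-band boundaries.** The phenotype inequalities are strict in
their usual statement, leaving `S` exactly at a boundary undefined. Bands
are closed on their lower edge (`S = 0.53` → immature bone, `S = 0` →
resorption): a measure-zero choice made deterministic.

**Breakpoint placement.** Interior breakpoints of the bi-/tri-linear laws
default to the equal partition of `[0, h]` (midpoint; thirds). The
reference design reports them only graphically; they are arguments if other
values are wanted.

## The optimizer

Each objective evaluation re-meshes and re-solves, so `Ω(A)` is piecewise
constant: it changes only when an element centroid crosses a pore rim.
The optimizer is built for exactly this landscape:

* **SQP core** (`sqp_box()`): damped-BFGS model Hessian; central
  finite-difference gradients with a step (default 5 µm, 20 µm in the
  desk-scale studies — about a third of the element size, large enough to
  see across the steps of the landscape); the box-constrained QP subproblem
  is solved *exactly* by enumerating the 3ⁿ bound-activity patterns and
  checking the KKT conditions (n ≤ 4 design variables); backtracking line
  search accepting simple decrease. Stopping: objective improvement below
  `ftol` (0.01 BO points), step below `steptol`, or `maxit`.
* **Multistart**: a mid-range start (150 µm uniform) plus configurable
  uniform starts; in the factorial study every richer law is additionally
  warm-started from each poorer law's optimum re-expressed on its
  breakpoints. Expansion is exact for constant → any and linear → any law,
  which makes the optimal `BO%` non-decreasing along the nesting chain by
  construction.
* **Pattern-search polish**: after the SQP starts finish, the best iterate
  is refined by cycling coordinate moves of `±fd_step` and `±fd_step/2`.
  On a stepwise objective this recovers the improvements that quadratic
  models smooth over.
* Infeasible geometries encountered during a search (pore overlap) return a
  penalized objective (10⁶) rather than an error.

## What the desk-scale studies do and do not show

The reference three-dimensional analyses (40 µm tetrahedra, ~300 h per
tri-linear optimization) are far beyond a desk budget. The package's study
preset is the 2D plane-strain section at 60 µm elements (≈ 9 000 triangles,
≈ 0.8 s per evaluation), with `maxit = 15` and two SQP starts plus warm
starts — a full constant-vs-trilinear study over three loads at
`E = 1000` MPa runs in about 5 minutes on one CPU. At this scale the
*orderings* are reproducible and are what the acceptance suite asserts:

* optimal `BO%` never decreases from the constant to the tri-linear law
  (exact, by warm-start nesting);
* under pure compression the optimal profile sits at the radius upper bound
  with `PVPD ≈ 0`, while pure shear yields a graded profile with
  `PVPD` of order 10–20 % — gradation is shear-driven;
* under shear the realized row-radius profile falls from the loaded half to
  the clamped half (positive mean drop, negative fitted slope). The two
  pore rows adjacent to the plate and the clamp sit in boundary-stiffened
  layers whose optimal radii fluctuate by ~5–30 µm across meshes, so
  element-wise monotonicity of the four coefficients is not resolved at
  desk scale; the trend statistic is.

Absolute `BO%` values at desk scale (≈ 20–45 %) are *not* comparable to the
reference three-dimensional results: the coarse section under-resolves the
strain concentrations at pore rims and the out-of-plane drainage, both of
which shift the stimulus distribution. Equally, the synthetic study
emulates only the stated loading and material conditions — it says nothing
about biological variability, cell migration, angiogenesis or scaffold
resorption, none of which are modelled (the stimulus is evaluated once, on
granulation-filled pores, at the end of the load ramp).

## Validation fixtures

Two analytical oracles guard the solver:

* **Terzaghi column** (`build_consolidation_column()`): an oedometric
  strip, drained and loaded at one end. The computed pore-pressure
  isochrones match the classical series solution within 2 % of the initial
  excess pressure at time factors 0.1, 0.5 and 1.0 (60 elements, 400
  steps), and the Darcy flux matches the series' gradient.
* **Patch block** (`build_patch_block()`): a homogeneous, fully drained
  block under slow uniaxial compression reproduces `ε = σ/E` to better than
  10⁻⁶ relative.

Linearity (doubling tractions doubles fields) and superposition
(mixed = compression + shear) hold to solver precision and are tested.

## A worked example

```{r example, eval = FALSE}
spec <- scaffold_spec(elem_size = 80)         # desk-scale 2D section
law <- porosity_law("linear", c(250, 150))    # wider pores near the load
mesh <- build_scaffold_mesh(spec, law)
sol <- solve_poroelastic(
  mesh,
  list(scaffold = scaffold_properties(E = 1000),
       granulation = granulation_properties()),
  load_case("shear")
)
field <- stimulus_field(sol, mesh)
objective_metrics(sol, mesh)
plot_phenotype_field(field)

ctx <- design_context(spec, "constant", scaffold_E = 1000,
                      load = load_case("shear"))
rec <- optimize_porosity(ctx, optimization_config(fd_step = 20, maxit = 10))
glance(rec)
autoplot(rec$best_law)
```

## Known limitations

* The pore realization is pixelated; quantities that depend on the exact
  rim geometry (local stress concentration factors) converge slowly.
* The objective's piecewise-constant structure means reported optima carry
  an intrinsic ±`fd_step/2` uncertainty in each coefficient.
* The plane-strain section cannot represent out-of-plane drainage; the two
  drainage conventions provided bracket the physical behaviour.
* Temporal tissue evolution, cell dispersal, angiogenesis, growth factors
  and scaffold resorption are out of scope by design; the stimulus is a
  snapshot at the end of the load ramp.
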