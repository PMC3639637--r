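---
title: "Simulating stented aneurysm hemodynamics with aneuflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating stented aneurysm hemodynamics with aneuflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Endoluminal stenting of small intracranial aneurysms aims to reduce the blood
exchange between the parent vessel and the aneurysm sac far enough that the
sac thromboses and occludes. Whether a given strut pattern achieves that is a
hemodynamic question: how much does the stent lower the residual velocity
inside the sac and the inflow velocity across the neck? `aneuflow` provides a
desk-scale simulator for this question on synthetic aneurysm geometries,
using two independent numerical routes to the same steady flow — a lattice
Boltzmann method (LBM) and an incompressible Navier–Stokes (NS) projection
solver — so that every reported observable can be cross-checked between
discretizations with entirely different error structure.

## Physical setup

All default parameters describe steady laminar flow of blood, treated as a
Newtonian fluid, in a small artery:

| parameter | default | unit | meaning |
|---|---|---|---|
| density ρ | 1060 | kg/m³ | whole blood |
| dynamic viscosity μ | 0.004 | Pa·s | Newtonian approximation |
| vessel width D | 3 | mm | small artery / channel width |
| peak inflow u_max | 50 | mm/s | parabolic (Poiseuille) inlet profile |
| Reynolds number | 19.875 | – | ρ·(u_max/2)·D/μ |

The Reynolds number uses the mean of the circular-pipe parabolic profile
(u_max/2 = 25 mm/s) as the characteristic velocity in both 2D and 3D, which
is the convention under which the default parametrization yields 19.875.
At Re ≈ 20 the flow is firmly laminar and a steady solution exists; pulsatile
(cardiac-cycle) inflow, non-Newtonian rheology and wall compliance are out of
scope.

## Geometry as level sets

The domain is a straight channel (2D) or circular tube (3D) with a circular
or spherical sac seated on the outer wall. All shapes are signed distance
fields (negative inside the fluid); the mask rasterizes their CSG union on a
regular grid of cell-centred nodes (a node is solid when its centre is).
The sac centre sits `sqrt(r² − (w/2)²)` beyond the wall so that the chord cut
by the wall line is exactly the neck width `w`. Two growth stages are
provided:

* medium: sac radius 2.25 mm, * larger: sac radius 3.0 mm,

both with a 2.0 mm neck. Because both stages share the neck chord, the larger
sac strictly contains the medium one outside the lumen — growth enlarges the
sac without moving the neck. The stage radii were chosen so that the standard
45° mid cutline spans 5 mm (medium) and 6 mm (larger) between its exits from
the flow domain, matching the cutline lengths of the study this geometry
emulates; the exact sac dimensions of that study are not published, so these
defaults are a calibrated reconstruction, not a copy.

The stent is five circular struts of 0.2 mm diameter spread evenly across the
neck, flush with the wall line, leaving four gaps of 0.3 mm — the coarsest
strut pattern that still shows the characteristic multi-gap exchange flow.
`check_watertight()` verifies every mask by flood fill before a solver sees
it.

A note on the 2D vessel: the emulated study uses a gently curved artery; the
default here is straight because a straight channel admits the exact
Poiseuille solution and therefore a quantitative validation of both solvers.

## The lattice Boltzmann solver

The LBM evolves particle distribution functions f_i on the D2Q9 (2D) or
D3Q19 (3D) stencil with single-relaxation-time (BGK) collisions,

f_i(x + e_i, t+1) − f_i(x, t) = −(f_i − f_i^eq)/τ,

with the second-order equilibrium
f_i^eq = w_i ρ (1 + 3 e_i·u + 9/2 (e_i·u)² − 3/2 u·u), density ρ = Σ f_i and
momentum ρu = Σ f_i e_i. The lattice viscosity is ν = (τ − ½)/3.

Unit mapping uses diffusive-style scaling: `cells_across_width` (default 30)
fixes Δx, and the prescribed peak lattice velocity `u_lattice_max` (default
0.05, Mach ≈ 0.087) fixes Δt; τ then follows from matching the physical
viscosity (τ ≈ 0.613 at the defaults). τ is confined to (0.5, 2]: BGK is
formally stable above 0.5, but accuracy degrades well before 2, so larger
values require an explicit override. The compressibility error of the method
scales with Mach², about 0.8 % at the defaults — visible as a ~0.6 % axial
density gradient along the channel that carries the pressure drop.

Boundary handling:

* **walls** — half-way bounce-back: a PDF whose streaming target is solid is
  reflected into the opposite direction at its origin, placing the no-slip
  wall half a cell beyond the last fluid node. The steady state is identical
  to the variant that swaps PDFs at the solid nodes themselves (that variant
  merely delays the reflection by one step), and the half-way form keeps
  streaming a pure permutation of PDF values, so mass conservation is exact
  and no PDFs need to live inside the solid padding.
* **inlet** — velocity Dirichlet: equilibrium PDFs at the prescribed
  parabolic profile, with density extrapolated from the first interior node.
  Simple and robust at Re ≈ 20; a characteristic-based condition would only
  matter at much higher Reynolds numbers.
* **outlet** — zero-gradient velocity with the density re-centred on the
  reference value 1: the non-equilibrium part of the upstream node is copied
  unchanged and the equilibrium part is rebuilt at unit density. A pure PDF
  copy leaves the pressure level of the open system undetermined, and the
  equilibrium inlet then inflates the density without bound; pinning the
  outlet density makes the pressure level well-posed while remaining an exact
  copy for a node already at unit density.

Collision folds the rounding defect of Σ f_i^eq into the rest direction, so
nodal mass is conserved exactly rather than to round-off; over 10⁴ steps the
global mass of a closed box is constant to ~10⁻¹⁴ relative.

The production path is a fused C++ kernel (collide → stream → inlet →
outlet); the exported R operations implement the same algebra step by step,
and a test asserts the two paths agree to 10⁻¹⁴ after tens of steps. Steady
state is declared when the maximum nodal velocity change per check interval
(default 200 steps), relative to the current maximum speed, falls below the
tolerance (default 10⁻⁶; the acceptance runs use 10⁻⁷).

## The Navier–Stokes reference

The cross-check solver integrates the incompressible Navier–Stokes equations
(ρ(∂u/∂t + u·∇u) = −∇p + μ∇²u, ∇·u = 0; the stress-divergence and Laplacian
viscous forms coincide for constant μ and solenoidal u) on the *same*
cell-centred mask, with a staggered (MAC) arrangement: explicit central
advection and diffusion, then a pressure projection whose Poisson operator is
assembled once over the fluid cells and factored with a sparse Cholesky
decomposition, making every projection a direct solve (post-projection
divergence ~10⁻¹⁵ in normalized units). Walls are enforced by ghost-face
reflection, which places the no-slip plane exactly on the faces bounding the
solid region — the same wall position the LBM's half-way bounce-back uses, so
the two solvers discretize the same geometry. Inflow is the same parabolic
Dirichlet profile; outflow copies face velocities (zero gradient) with the
pressure pinned to zero in the outlet column. The time step defaults to half
the explicit diffusive/advective stability bound. A moving-top-wall option
exists solely to validate against plane Couette flow.

This structured-grid solver deliberately replaces the Q2/P1 finite-element +
multigrid machinery of the emulated study: the contract is the *solution* —
no-slip walls, prescribed inflow, free outflow, divergence-free steady field
— not the discretization, and on cutline profiles the two routes agree to a
fraction of a percent, far inside the 5 % agreement band asserted by the
tests.

## Observables

* **Cutline profiles** — velocity magnitude sampled at evenly spaced points
  along `pre` and `post` lines (full vessel width, 1.25 D before/after the
  neck) and the `mid` line crossing the neck centre at 45° to the axis
  (5 mm medium / 6 mm larger). Interpolation is bilinear/trilinear with solid
  nodes contributing zero, so profiles fall to zero inside walls and struts.
* **Sac mean velocity** — unweighted mean of |u| over the fluid nodes outside
  the unperturbed lumen, in mm/s: the stagnation measure stents aim to
  reduce. The averaging region of the emulated study is not precisely
  defined; the unweighted node mean is the simplest reproducible choice.
* **Neck peak velocity** — maximum of the mid-cutline profile over the neck
  aperture: samples within one neck half-width of the neck centre *and* on
  the sac side of the wall line. The intravascular part of the 45° cutline is
  excluded deliberately: its velocities (30–40 mm/s here) belong to the
  parent-vessel jet, whereas the aperture samples (~14 mm/s, larger stage)
  are the exchange flow the neck actually carries.
* **In-vessel neck drop** (`neck_velocity_drop()`) — the sag of the lumen
  cross-section peak at the neck's axial position relative to the upstream
  section. This is the "drop in the vessel at the neck" that grows with
  aneurysm stage. With both stages sharing the same 2 mm neck the effect is
  small (≈1.88 mm/s, larger exceeding medium by well under 1 %), so while its
  direction is a robust, deterministic result, its magnitude should not be
  over-interpreted.
* **Vorticity** — ∂u_y/∂x − ∂u_x/∂y by central differences, reported at its
  maximum magnitude inside the sac.

## What the synthetic geometry does and does not show

The generator emulates a sidewall ("true") aneurysm with an idealized
circular sac on a straight vessel. Relative to real (MRI-derived) anatomy it
omits vessel curvature and tapering, irregular sac shape, neck asymmetry and
wall motion. Consequently, passing tests demonstrate that the two numerical
methods agree with each other and with analytic laminar solutions *under the
study conditions*, and that the stent effect has the right direction and
order of magnitude — they do not certify predictions for any individual
patient geometry.

Two quantitative caveats follow from the reconstruction. First, the measured
unstented observables land close to the reported ones (sac mean ≈ 1.1–1.4
mm/s against ≈ 1; larger-stage neck peak ≈ 13.5 mm/s against ≈ 14). Second,
the default stent is much *denser* relative to this 2 mm neck than the coarse
stent of the emulated study appears against its wide neck: five 0.2 mm struts
leave 0.3 mm gaps whose gap Reynolds number is ≈ 0.4, so the sac decouples
almost completely (sac mean ≈ 0.04 mm/s, neck peak ≈ 0.2 mm/s) instead of
dropping mildly (≈ 0.75 and ≈ 5 mm/s). The direction of the stent effect is
reproduced strictly; its magnitude is a property of the strut-to-neck ratio,
which is unknown for the original geometry.

## Numerical choices and problem sizes

* Resolution: 30 cells across the 3 mm width (Δx = 0.1 mm) for all 2D
  production runs — the coarsest grid at which the Poiseuille validation is
  comfortably under 1 % and the 0.2 mm struts rasterize reliably; the 3D
  preset uses 16 cells across the diameter to stay desk-scale.
* Steady-state tolerances: 10⁻⁷ (LBM) and 10⁻⁶ (NS) relative change per
  check interval; typical 2D runs converge in 3·10⁴ LBM steps (~3 s of
  physical time) or ~2·10³ NS steps, well under a minute each on one core.
* Degenerate inputs are rejected eagerly: τ outside (0.5, 2], Mach-violating
  lattice velocities, sacs overlapping the inlet/outlet, stents without an
  aneurysm, leaky masks, zero-length cutlines, all-zero reference profiles.
* Determinism: no randomness is used anywhere in the default pipeline; two
  runs from one configuration are bit-identical (a seed field exists for
  optional randomized initial perturbations).

## A worked comparison

```{r}
library(aneuflow)

cfg <- preset_config("medium-2d")
out <- run_comparison(cfg)
out$comparison$mid$rel_l2   # LBM vs NS on the neck cutline: ~0.006
out$result$summaries$lbm    # sac mean ~1.4 mm/s, neck peak ~12 mm/s

stented <- run_scenario(preset_config("larger-2d-stented"))
stented$summaries$lbm$sac_mean_mm_s  # sac nearly stagnant under this stent
```

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/aneuflow` (`simulate --preset larger-2d-stented --out DIR`), which
writes the velocity and vorticity fields (legacy VTK), cutline profiles
(CSV), the summary (JSON) and the convergence history of every run.
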