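---
title: "Modelling drug penetration into peritoneal tumor nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug penetration into peritoneal tumor nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipchemo)
```

`ipchemo` models the transport of a cytotoxic drug from the instillate
bathing a peritoneal tumor nodule into its interstitium. This vignette is
the package's account of the science: the model and its assumptions, the
parameters that matter, the numerical choices, and what the verification
suite does and does not establish.

## The physical model

A tumor nodule is treated as a rigid, isotropic porous medium with two
concentric zones: a *viable* rim containing functional (leaky)
microvasculature and live cells, and a *necrotic core* with neither.
Neither zone has functional lymphatics.

**Interstitial fluid.** The momentum balance reduces to Darcy's law,
`u = -K ∇P_i`, with `K = k/μ` the conductivity of the tissue. Fluid
filters out of the microvessels according to Starling's hypothesis, so the
steady continuity equation is `∇·u = F_v` with

`F_v = L_p (S/V) (P_v − P_i − c (π_v − π_i))`

in viable tissue and zero in the core. The instillate pressure on the
outer surface is fixed at 0 Pa: the true value lies between roughly 0 and
20 Pa, which is negligible against the ~1.5 kPa interstitial scale. The
source is linear in `P_i`, so the problem is a single linear elliptic
solve; `P_i` can never exceed the Starling effective pressure
`P_ss = P_v − c(π_v − π_i)` (1530.6 Pa at baseline parameters), which is
reached on a plateau covering most of the nodule except a boundary layer
of thickness `α⁻¹ = sqrt(K/(L_p S/V))` ≈ 0.27 mm.

**Drug.** On the frozen velocity field the free drug concentration obeys
a convection–diffusion–reaction equation with two first-order sinks:
cellular elimination `β C`, and resorption into the (drug-free) blood
`P_c (S/V) C · Pe_v/(e^{Pe_v}−1)`, where the transvascular Péclet number
`Pe_v = F_v(1−σ)/(P_c S/V)` is small (~0.02) at baseline. Both sinks and
the filtration source vanish in the core; the diffusivity does not change
across the interface, and all fields are continuous there. Because
`∇·u = F_v ≠ 0`, the advection term is kept in full divergence form.
The interior starts drug-free and the surface is held at the instillate
concentration `C0` — a deliberate simplification (a real instillate
depletes slowly).

Two model-structure points deserve emphasis:

* The cellular sink is written as a first-order elimination `β C`; `β` is
  the literature elimination constant, and dimensional consistency demands
  the concentration factor.
* The vascular exchange term acts as a *loss* of interstitial drug
  (resorption into blood at negligible vascular concentration); any sign
  convention making it a source would be unphysical.

## Parameters

All computation is in SI units; printed table values in other units pass
through `to_si()` exactly once, at the parsing boundary. The baseline
tissue set (`baseline_tissue()`) describes vascularized tumor tissue:
`K = 3.10e-14 m²/(Pa·s)`, `L_p = 2.10e-11 m/(Pa·s)`, `S/V = 2.00e4 1/m`,
`P_v = 2080 Pa`, `π_v = 2670 Pa`, `π_i = 2000 Pa`, `c = 0.82`. The fluid
density and drug molecular weight are stored for provenance but unused
(incompressible flow; diffusivities are given directly). Drug presets:
cisplatin (`D = 2.5e-10 m²/s`, `IC50 = 6.2e-3 mol/m³`) and paclitaxel
(`D = 0.77e-10 m²/s`, `IC50 = 1.4e-6 mol/m³`), sharing
`β = 7.32e-4 1/s`, `σ = 8.17e-5` (used as tabulated; its smallness makes
`1−σ ≈ 1`), `P_c = 1.43e-6 m/s` and `C0 = 0.8 mol/m³` unless overridden.

Vascular normalization therapy is modelled by `normalize_vasculature()`:
`L_p`, `S/V` and `c` move linearly between the tumor baseline and
normal-tissue endpoints (`2.70e-12`, `7.00e3`, `0.91`). The published 50%
row rounds `L_p` to 1.19e-11; the exact midpoint 1.185e-11 is used, since
the construction is defined as the halfway interpolation. The
permeability study sweeps `k ∈ {6.4e-18, 3.1e-17, 6.4e-17} m²` with
`K = k/μ` recomputed, keeping the two fields consistent by definition.

## Geometries

Six parametric shapes (`geometry_preset()`): spheres of radius 10 mm (LS)
and 2 mm (SS) with cores at half the radius; prolate ellipsoids with
half-axes 20/10 mm (LE) and 4/2 mm (SE), cores similar at half scale; and
cropped "peritoneal" nodules (LT/ST). The cropped shape is constructed by
halving the corresponding oblate spheroid: in-plane half-length 20 mm,
height 10 mm above a flat face (LT; ST is a fifth of that), with a
similar dome-shaped core (8.7/4.53 mm) sharing the flat face. The exact
crop plane and core placement are not uniquely determined by the printed
extents; this construction — a dome resting its flat face on the
peritoneum — was chosen as the geometrically simplest reading and is the
one the solvers assume.

**Flat-face boundary condition.** Whether the flat face is bathed in
instillate is genuinely open. The default here is *no*: the face models
the contact area with the peritoneal wall and receives zero-flux
conditions for both pressure and drug. Two internal consistency arguments
force this choice: the long-axis profile of LT lies in the flat-face
plane, and a bathed face would pin that whole profile at `C = C0`
(PD% = 100) and `P = 0` (LP50 undefined) — neither of which resembles the
reported behaviour of such nodules. With zero flux, the dome is exactly
the upper half of an oblate spheroid and the face is a symmetry plane.
`bath_flat_face = TRUE` restores the alternative reading.

## Discretization and numerics

*Spheres* use a vertex-centred conservative finite-volume scheme on a
uniform radial grid (default spacing `r/1000`), with the necrotic
interface snapped onto a grid node. *Ellipsoids and domes* use
piecewise-linear axisymmetric finite elements on a mapped triangulation
of the meridional quarter cross-section: rays blend from the core ellipse
to the outer ellipse so the interface coincides exactly with a mesh ring
(interface-fitted; no property smearing), and radial spacing is graded
geometrically — fine (default `r_s/400`) at the outer surface and the
interface where the pressure (`α⁻¹` ≈ 0.27 mm) and concentration
(`φ⁻¹ = sqrt(D/k_e)` ≈ 0.09 mm for cisplatin) boundary layers live,
coarsening tenfold mid-band. A full-3D backend is deliberately absent:
every supported shape is exactly axisymmetric, so the 2-D reduction loses
nothing and keeps each case solvable in seconds.

The pressure problem is one sparse direct solve; the algebraic residual
drop is checked against four orders of magnitude. Velocities are the
discretization's own gradients (face differences / cellwise P1
gradients). Transport uses implicit Euler with `dt = 30 s` (the transport
operator is constant, so it is factorized once); the loss timescale
`1/(β + P_c S/V)` ≈ 34 s makes the solution quasi-steady well before the
evaluation time, so first-order time accuracy costs nothing at the
reported metrics — the suite also checks transient/steady agreement below
1%. Advection is discretized centrally without artificial stabilization;
the solver *errors out* if any cell Péclet number `u h/D` exceeds 2
rather than silently smearing penetration depths. Mass matrices are
lumped, which preserves the discrete maximum principle
(`0 ≤ C ≤ C0`, checked everywhere). Row equilibration is applied before
factorization because the assembled systems mix O(1) Dirichlet rows with
O(1e-20) flux rows.

Metrics are measured on 400-sample axis profiles with linear
interpolation at threshold crossings; LP50 is reported as a fraction of
the axis half-length (the printed values 0.70–0.99 are dimensionless, so
the defining "distance" is normalized). If a concentration profile
crosses IC50 more than once the innermost crossing is used ("maximal
depth") and a warning is raised. The characteristic length in the global
Péclet number is the half-length of the axis of interest, giving per-axis
Pe values; a case's headline Pe is the maximum over its axes. Evaluation
time for transient metrics defaults to 3600 s, the upper end of the
typical 30–60 min instillation; steady metrics are always reported
alongside, and with baseline loss rates the two agree to three decimals
in APD.

Omitting the necrotic core (the `necrotic` study) is implemented exactly
as "treat the core as viable tissue" — sinks and filtration switched on
everywhere on the *same* mesh — not by re-meshing, so the comparison
isolates the physics from discretization changes.

## Verification

Closed-form oracles, implemented as separate code paths that never touch
the mesh solvers, anchor the test suite:

* the spherical Starling pressure solution (constant-pressure core, sinh
  shell, evaluated in a shifted basis that stays well-conditioned at
  `αR ≈ 37`), matched by the finite-volume solver to < 0.5% with observed
  order ≈ 2;
* the steady reaction–diffusion profile `C0 (R/r) sinh(φr)/sinh(φR)`
  (< 1%), and the transient pure-diffusion series solution (< 1%);
* global budget closure: transvascular filtration vs surface outflow,
  and the discrete drug-mass balance (< 1%, with the 1-D surface flux
  additionally cross-checked against `4πR²u(R)`);
* cross-backend agreement: a sphere solved axisymmetrically in 2-D
  reproduces the 1-D radial metrics;
* monotonicity properties: pressure bounded by `P_ss`, concentrations
  monotone in time, penetration deepening under vascular normalization
  and vascular-sink removal, relative penetration deeper in small
  geometries, and pressure invariance under drug swap.

These checks validate the *solvers* against the *stated equations and
parameters*. They cannot validate the model against tissue reality: the
model has a spatially uniform distributed vasculature, no ECM or plasma
protein binding (IC50 values come from protein-free in-vitro assays), a
constant instillate concentration, and a rigid matrix with no
pressure-driven deformation. Penetration depths should therefore be read
as estimates of transport-limited behaviour under the tabulated
parameters, not as patient-level predictions.

## Problem sizes and reproducibility

Default meshes are version-pinned so study tables are machine-independent:
~1000 nodes for 1-D spheres, ~4000 nodes (48 angular sectors) for
axisymmetric shapes; a six-geometry study solves in a few seconds on one
CPU. `run_convergence()` repeats any case at halved cell sizes: at the
defaults IFP_max is converged to < 0.1% and APD to < 0.01 mm, with
observed orders ≈ 2 (pressure) and ≈ 1.9 (penetration depth). Every
simulation is deterministic; `run_case()` run twice returns bit-identical
metrics.

## Known limitations

Beyond the modelling assumptions above: the cropped-shape construction is
one of several readings of the published extents (the core's flat face is
taken coplanar with the nodule's); PD% averages weight each
geometry–axis pair equally, as the original averaging weights are
unstated; and the permeability study's sensitivity bound is tight enough
that scheme-level differences between solvers (ours vs the original
finite-element implementation) are visible in the last reported decimal.
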