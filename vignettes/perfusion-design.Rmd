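---
title: "Modeling perfusion seeding of porous scaffolds: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling perfusion seeding of porous scaffolds: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`perfuseed` models the computational design loop for perfusion
bioreactors that seed cells into porous bone-substitute blocks: how
chamber and connector geometry shape the flow through the scaffold, how
the flow shapes where cells deposit, and how a dynamic PET readout of
labeled cells quantifies the outcome. This vignette explains the models,
their assumptions, the tunable parameters, and the limits of what the
synthetic pipeline demonstrates.

## The synthetic scaffold

The reference scaffold is a 10 × 10 × 20 mm deproteinized cancellous
bone block with 69% porosity and a bimodal pore structure (nanopores
around 17 nm and macropores around 0.1 mm). Micro-CT resolves such a
block at ~10 µm; flow simulation on that grid needs hundreds of millions
of unknowns. At desk scale we instead generate a *macro-porous
surrogate*: white noise on a 0.25 mm grid is smoothed with a Gaussian
kernel whose width is set by a surrogate pore scale (default 0.5 mm, the
smallest scale resolvable with two voxels), and the top fraction of the
field becomes fluid, so the stored porosity equals the target exactly up
to one voxel. If the fluid phase does not connect the two end faces
(6-neighbour adjacency), the threshold is relaxed stepwise — a
deterministic repair given the seed — and generation fails loudly if the
porosity would drift more than 2 percentage points. The surrogate matches
the block's porosity, dimensions and percolation, **not** its true pore
geometry; nanoporosity is below the continuum scale of every model here
and is ignored.

`generate_scaffold()` is deterministic in `(parameters, seed)`; ensembles
over seeds stand in for biological scaffold-to-scaffold variability.

## Reactor domains

`build_domain()` voxelizes chamber, connectors, scaffold and walls into a
labeled grid (z = flow axis, origin at the inlet port plane, world
coordinates at voxel centers). Design choices worth knowing:

* **Connectors.** Cylindrical connectors are circular bores; conical
  diffusers are *square-based* frustums expanding linearly from the
  throat to the scaffold face. The printed chambers are square in
  cross-section and their diffusers are specified by height × width, so a
  square base is the faithful shape — a circular cone of matching width
  would leave the face corners walled off and starve them of flow.
* **Tubing bore.** Every connector is fed through a port opening of at
  most 1.6 mm (a typical flow-tubing bore; configurable). This matters:
  the perfusate enters the connector body as a jet, and how much room the
  connector gives that jet to spread before the scaffold face is exactly
  what distinguishes short from long and narrow from wide connectors. The
  published dimensions do not state a throat diameter, so the default is
  a deliberate, documented choice.
* **Encasement.** `enc+` is a press-fit: the chamber hugs the scaffold
  and connector walls close around the diffuser, so all flow crosses the
  scaffold. `enc-` is a loose fit: a uniform annular gap (default 0.5 mm;
  the loose-fit gap width is not quantified in print) surrounds the
  scaffold and the connector span is an open plenum, so flow can bypass
  the block along its lateral faces.
* **Resolution.** Domains built at the scaffold's native voxel size keep
  the two-phase occupancy (`resolved`); coarser domains block-average the
  occupancy into a per-voxel porosity field used by the homogenized flow
  mode. Flow studies default to 0.5 mm voxels, which keeps each linear
  solve near 10^5 unknowns.

## Flow: Stokes–Brinkman

At 1 ml/min through millimetre-scale ports the Reynolds number is of
order 1–10, so the solver drops inertia entirely and solves creeping flow
— a deliberate simplification relative to full CFD that makes the problem
a single symmetric linear system. In open regions the momentum balance is
Stokes; scaffold voxels add an isotropic Brinkman drag $\mu/k$ with
Kozeny–Carman permeability
$k = \phi^3 d^2 / (180\,(1-\phi)^2)$ evaluated per voxel on the local
porosity field ($d$ = pore scale). Boundary conditions follow the study
protocol: uniform normal velocity $Q/A$ over the inlet port, no slip on
walls, and an outlet at zero reference pressure (implemented as uniform
outflow with the pressure field re-referenced to the outlet-plane mean,
which keeps the discrete system symmetric).

Discretization is a marker-and-cell staggered grid; walls and resolved
solid voxels enter as exact Dirichlet (no-slip) conditions on their
faces rather than by penalization, so velocity is identically zero in
solid. The saddle-point system is solved by conjugate gradients on the
pressure Schur complement with supernodal Cholesky factorizations of the
three momentum blocks and a diagonal (SIMPLE-type) preconditioner;
convergence is declared at a relative residual of $10^{-8}$. Because the
discrete system is linear, doubling $Q$ doubles the field exactly and the
reverse-perfusion field is exactly the negated forward field — the
oscillating protocols exploit this instead of re-solving.

Consequences of the creeping-flow choice: inertial jet penetration and
recirculation are absent, so connector effects are weaker than in
inertial CFD, and they express themselves through how much spreading room
the geometry gives the inflow jet. The design orderings (conical ≤
cylindrical, longer connectors better, wide bores better on homogeneity
and shear) survive; the absolute Hoover and shear values are not
comparable to pore-resolved CFD on real micro-CT geometry and are not
claimed to be.

The shear-rate field is $\dot\gamma = \sqrt{2\,D\!:\!D}$ with $D$ the
rate-of-strain tensor from central differences (one-sided at
boundaries).

## Homogeneity: the Hoover coefficient, twice

The Hoover (Robin-Hood) index of nonnegative quantities $v_i$ with
reference weights $w_i$ is half the L1 distance between quantity shares
and weight shares; 0 means perfectly even, $1 - 1/n$ is attained when one
bin holds everything. The package uses it in two distinct ways that the
literature tends to conflate under one name:

1. **Flow homogeneity** (`flow_homogeneity()`): the index of the
   velocity-magnitude distribution *within* each cross-sectional plane,
   equal weights, averaged over planes — the design-ranking score
   $\bar H_K$. The default plane set is 24 planes at 1 mm spacing
   centered on the scaffold, which spans the block plus 1.5 mm of each
   connector; exact placement for a 20 mm block is not stated in print,
   so both count and spacing are configurable. The connector sweep scores
   every voxel plane across the scaffold plus 1 mm of each connector so
   that all lengths (including 1 mm) are compared on identical support.
2. **Axial distribution homogeneity** (`axial_distribution_hoover()`):
   the index *across* planes of the per-plane deposited quantity (cells
   or activity), weighted by per-plane scaffold fluid volume — the
   single-number readout for seeding outcomes and PET frames.

## Cell seeding

No mechanistic transport model for the cells is given in print; the
simulator here is a declared synthetic stand-in whose free parameters are
calibrated to one published operating point and validated against
published directions of effect only.

Representative Lagrangian particles (default 1500 per run; each carries
$cQT/N$ real cells) are injected at the active upstream port at rate
$c\,Q$ over the 60-minute seeding phase, then tracked through a
40-minute washout. Per base step (default 2 s, sub-stepped so no particle
moves more than a voxel): advection by the trilinearly interpolated
velocity (divided by local porosity inside the homogenized scaffold to
give interstitial speed), Stokes settling
$v_s = \Delta\rho\, g\, d^2/(18\mu)$ (≈ 4.8 µm/s for a 15 µm,
1050 kg/m³ cell), and an isotropic random walk with dispersion
coefficient $D$ (default 5 × 10⁻³ mm²/s — the scale of mechanical
dispersion $\alpha v$ with dispersivity $\alpha$ of one pore length, far
above Brownian motion). Capture: in voxels with solid surface, particles
adhere with hazard rate
$\lambda = p_a\, v_{dep}\, S_v$, where $S_v$ is surface area per volume
(from face counts in resolved regions, $6(1-\phi)/d$ in homogenized
scaffold), $v_{dep} = v_s + D/(d/2)$, and $p_a$ is the adhesion
probability; the hazard is scaled by $\max(0, 1-\dot\gamma/\dot\gamma_c)$
(default threshold 50 s⁻¹) and by remaining surface capacity. Capacity
(default 3000 cells/mm², sub-confluent for 15 µm cells) is tracked per
axial slice — separately for scaffold and non-scaffold surface — because
a representative particle carries more cells than a single voxel's
surface holds; the acceptance probability `remaining/weight` keeps the
deposited cell count unbiased while modeling a saturation front that
fills downstream. Particle bookkeeping is exact:
injected = deposited + in-domain + outflowed, as integers, every run.

**Calibration.** `calibrate_deposition()` searches $p_a$ (coarse grid,
then bisection) so the ensemble-mean efficiency at the reference
condition (0.4 × 10⁶ cells/ml, 0.5 ml/min, type 2 chamber with
encasement, unidirectional) matches the published 80% optimum. The
shipped default $p_a = 0.15$ is the output of that procedure; nothing
else is fitted. What the calibrated model then *predicts* — efficiency
falling with flow rate and with concentration, the encasement advantage,
the inlet-proximal bias of unidirectional seeding, and the homogeneity
gain from oscillation — are genuine out-of-sample directions of effect.

Efficiency is defined as scaffold-deposited over injected; cells that
stick to connector or chamber walls correspond to the cleaning-solution
fraction of the experimental count-based definition
(`efficiency_from_counts()`).

## Synthetic PET

The PET stage models *already reconstructed* dynamic images; scanner
physics (attenuation, randoms, dead time, OSEM reconstruction) is out of
scope. Per 5-minute frame: voxel activity is (deposited + suspended)
cells × per-cell activity × the physical decay factor of fluorine-18
(half-life 109.77 min, a nuclide constant), plus a circulating
free-tracer background in open voxels during the perfusion phase;
adherent-cell activity leaks with a small single-exponential rate during
washout (default 0.004/min, chosen to produce the observed slow decline
to a plateau — a stand-in, not a measured rate). The per-cell activity
defaults to a 1 MBq label offer per 2 × 10⁵ cells times an uptake
fraction (default 5%, a free parameter). A Gaussian PSF (default
σ = 0.8 mm) and optional Poisson resampling complete the forward model.

ROIs follow the imaging protocol: the whole scaffold bounding box, its
axial thirds (upper = inlet-proximal), and the outflow tract. Hoover
time courses are computed on decay-corrected frames by default (whether
the published analysis decay-corrected first is unstated; both are one
call apart).

## Study runners and statistics

`connector_sweep()` ranks connector shape × length × bore by
$\bar H_K$ and maximum scaffold shear over a scaffold-seed ensemble
(default 5 seeds at 0.5 mm study resolution — about sixty sparse solves).
`efficiency_sweep()` reruns seeding over concentration or rate grids and
reports the Pearson correlation; note the published correlation values
labeled "R²" are signed correlation coefficients, so the package reports
`r` and `r_squared` separately. `configuration_comparison()` runs the six
studied configurations end-to-end (flow → seeding → PET) and reports
60-minute enrichment and axial Hoover with Welch t tests (raw p-values,
mirroring the published analysis; Holm adjustment is one `p.adjust` call
away). Every report row carries its seed, and identical seeds reproduce
identical rows.

Problem sizes throughout (0.5 mm flow grids, 1500 particles, 5–10 seed
ensembles, 2 s base step) were chosen once as the desk-scale operating
point of the package; they resolve every effect the package claims while
keeping a full study in minutes on one core.

## Known limitations

* The surrogate scaffold matches porosity and dimensions, not real pore
  architecture; absolute Hoover/shear values are not comparable to
  pore-resolved CFD and published experimental values (enrichment in
  MBq, Hoover 0.24 for the oscillating mode) are *not* reproduction
  targets — only orderings and directions of effect are claimed, and
  those are what the acceptance suite tests.
* Creeping flow: no inertial jets or recirculation; connector effects are
  correspondingly weaker than in inertial CFD.
* The deposition model is phenomenological; its parameters other than the
  calibrated adhesion probability are defaults with physical-scale
  justification, not measurements.
* No biology after adhesion: proliferation, differentiation, oxygen and
  nutrient transport, and multi-day culture are out of scope.
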