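# perfuseed

Desk-scale in-silico pipeline for designing perfusion bioreactors that
seed cells into porous bone-substitute scaffolds.

Seeding a ceramic bone block with stem cells in a closed chamber must be
fast (chairside: under an hour), efficient (most deployed cells retained)
and homogeneous (cells everywhere, not just under the inlet). All three
depend on chamber geometry and the perfusion protocol. `perfuseed`
implements the computational side of that design problem for people
working on scaffold perfusion systems:

* **Synthetic scaffold volumes** — Gaussian-random-field porous volumes
  with controlled porosity (default 69%, a 10 × 10 × 20 mm cancellous
  block), percolation-repaired along the flow axis; NIfTI/JSON IO for
  real segmented volumes.
* **Reactor geometry** — voxelized chamber domains with cylindrical or
  conical (diffuser) connectors, optional press-fit lateral encasement
  (`enc+`) vs a loose fit with a bypass gap (`enc-`), lengthwise or
  transverse perfusion; presets for the three studied chamber types.
* **Flow** — steady creeping Stokes–Brinkman flow on a staggered voxel
  grid (sparse Cholesky + Schur-complement CG), with shear-rate fields.
* **Homogeneity** — the Hoover (Robin-Hood) coefficient,
  \(H = \tfrac12 \sum_i \lvert q_i - p_i \rvert\) for quantity shares
  \(q\) against reference shares \(p\): 0 is perfectly even, values near
  1 maximally concentrated. Applied per cross-sectional plane to velocity
  magnitudes (mean over 24 planes at 1 mm spacing ranks designs) and
  axially to deposited cells or activity.
* **Cell seeding** — a Lagrangian particle simulator (advection, Stokes
  settling, pore-scale dispersion, shear- and capacity-limited surface
  capture) for 60 min seeding + 40 min washout protocols, unidirectional
  or oscillating, with exact particle accounting and seeding-efficiency
  readouts.
* **Synthetic dynamic PET** — 5-min-frame activity images of
  radiolabeled cells (fluorine-18 decay, PSF blur, optional Poisson
  noise), ROI time–activity curves (whole block, axial thirds, outflow
  tract), decay correction and Hoover time courses.
* **Study runners** — the connector-geometry sweep, the
  concentration/rate efficiency sweeps and the six-configuration
  comparison, with Pearson/Welch statistics and ggplot2 figures.

Results come back as tibbles; fitted/derived objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(perfuseed)

# synthetic scaffold block: 10 x 10 x 20 mm, 69% porosity
sc  <- generate_scaffold(seed = 1)
measure_porosity(sc)
#> [1] 0.69

# type 2 chamber (conical diffusers, press-fit encasement), flow at 1 ml/min
dom  <- build_domain(sc, preset("type2", encasement = TRUE), voxel_mm = 0.5)
flow <- solve_flow(dom, inlet_flow_ml_min = 1)
hov  <- flow_homogeneity(flow, dom, planes = default_planes(dom))
mean_hoover(hov)
#> [1] 0.4435211
max_shear_in_scaffold(flow, dom)
#> [1] 2.407337
```

The mean Hoover coefficient of ~0.44 says the within-plane velocity
distribution is moderately uneven (the printed design study spans
0.41–0.61 across connector variants); the peak scaffold shear of a few
s⁻¹ is far below levels that impair adhesion.

```r
# seed cells: 0.4e6 cells/ml at 0.5 ml/min, 60 min + 40 min washout
sr <- simulate_seeding(flow, dom,
                       perfusion_protocol("unidirectional", rate_ml_min = 0.5),
                       cell_suspension(0.4e6), deposition_params(), seed = 1)
sr
#> <seeding_result> unidirectional, 0.5 ml/min: injected 1500, deposited 1324,
#>   in domain 0, outflowed 176 particles
#>   seeding efficiency (scaffold) = 0.819
axial_distribution_hoover(sr$deposited_cells, dom)
#> [1] 0.2505568
```

About 82% of the deployed cells end up in the scaffold — the calibrated
reference operating point — but the axial Hoover of ~0.25 shows the
unidirectional deposit is biased toward the inlet. Re-running with
`perfusion_protocol("oscillating", rate_ml_min = 0.5)` (one reversal at
30 min) drops it to 0.103: oscillation is what evens out the axial
profile.

```r
# synthetic dynamic PET readout of the same run
pet <- synthesize_pet(sr, dom, noise = "poisson", seed = 1)
tc  <- enrichment_and_hoover_timecourse(decay_correct(pet), dom)
autoplot(roi_timecourses(pet, dom))
```

Study-level orchestration:

```r
rep <- connector_sweep(scaffold_seeds = 1:5)     # Hoover/shear per design
sweep_summary(rep)
autoplot(rep)
cmp <- configuration_comparison(seeds = 1:5)     # six chamber configurations
sweep_summary(cmp)
```

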