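# tumorperf

Solid tumors remodel their blood supply as they grow: host vessels are
co-opted and dilate, their walls degenerate, low-shear vessels collapse, and
growth-factor-driven sprouting crowds the invasive rim. The leaky tumor
vasculature, combined with the absence of intratumoral lymphatics, elevates
the interstitial fluid pressure (IFP) to a central plateau that drops sharply
across the tumor boundary and drives an outward interstitial flow — a
configuration widely believed to hinder drug delivery. `tumorperf` is a
desk-scale R implementation of a hybrid discrete-continuum model of this
system, for computational-oncology researchers who want to probe how vascular
morphology, wall/tissue/lymphatic conductivities and convective versus
diffusive transport shape the exposure of tumor cells to a drug.

The package covers the full pipeline:

- **Vessel networks** on FCC (3D) or triangular (slab) lattices: hierarchical
  arteriovenous synthesis with Murray's law radii
  (`r_parent^3 = sum(r_child^3)`), capillarization between opposing
  terminals, and shear-stress-driven remodeling to a capillary-count plateau
  (`construct_initial_network`).
- **Blood flow**: Poiseuille conductances `q = pi r^4 dp / (8 eta l)` with
  the Pries in-vivo viscosity law and Kirchhoff nodal-pressure solves
  (`solve_nodal_pressures`).
- **Tumor growth**: volume-fraction mixture tissue with a level-set
  interface, oxygen and growth-factor fields, and stochastic vascular
  remodeling in 1 h steps (`growth_step`).
- **Interstitial fluid**: stationary Darcy flow with Starling vessel sources
  and lymphatic sinks, `div(K grad p) + Q(p) = 0`, solved sparsely with a
  per-sample decomposition of extravasation, vessel uptake and lymphatic
  uptake (`assemble_and_solve_ifp`).
- **Drug transport**: two-compartment (extracellular/intracellular)
  convection-diffusion-reaction dynamics for a Doxorubicin-like drug under
  bolus or infusion schedules, with ICmax/ICAUC exposure maps and radial /
  distance-to-vessel profiles (`simulate_drug`, `exposure_metrics`,
  `theta_profile`).

## Worked example

Build a desk-scale network, freeze a compartmentalized tumor state, and
solve the interstitial flow:

```r
library(tumorperf)
params <- default_parameters()          # desk-scale preset

net <- construct_initial_network(params, seed = 7)$net
nrow(net$segments); sum(net$segments$cap); all(net$segments$perfused)
#> segments: 331   capillaries: 46   all perfused: TRUE

fx  <- make_fixture("frozen-spherical-tumor", size = 40, seed = 1,
                    params = params)
iff <- assemble_and_solve_ifp(fx$net, fx$state, fx$grid, params, seed = 3)
theta_profile(iff$p, fx$state$theta, 100)   # IFP vs distance to tumor edge
#>  theta mean
#>   -250 3.12
#>   -150 3.10
#>    -50 2.95
#>     50 2.67
#>    150 2.44
#>    250 2.31
#>    350 2.21
#>    450 2.13
#>    550 2.10
table3_aggregates(fx$net, fx$state, fx$grid, iff)$r_gamma
#> 0.00898
```

The profile shows the characteristic interstitial hypertension: a plateau
inside the tumor (`theta < 0`, about 3.1 kPa here) with the steepest drop
across the boundary shell and a lower far-field level set by the lymphatics.
`r_gamma` is the fraction of the blood flow entering the tumor that is lost
to the interstitium — small, which is what justifies solving blood flow and
interstitial flow uncoupled (on this thinned 2D slab scene it is of order
1e-2; in full-scale 3D hierarchies the denominator is much larger and the
fraction correspondingly smaller). Feeding `iff` into `drug_state()` /
`simulate_drug()` then yields concentration snapshots and ICmax/ICAUC maps;
`case_variation(params, "iii")` and friends switch to the studied parameter
variations (heavier particles, infusions, no convection, scaled wall /
tissue / lymphatic conductivities, restored tumor lymphatics).

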