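---
title: "Modeling interstitial fluid flow and drug transport in vascularized tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interstitial fluid flow and drug transport in vascularized tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model structure

`tumorperf` is a hybrid discrete-continuum simulator of solid vascularized
tumors.  Its pipeline has four stages, each usable on its own:

1. **Network synthesis.** A hierarchical arteriovenous network is grown on a
   lattice: tree roots alternate arterial/venous along the domain boundary,
   trees grow by stochastic attachment of single-bond or Y-shaped structural
   elements, capillaries temporarily bridge opposing terminals, radii follow
   Murray's law ($r_p^\alpha = \sum_c r_c^\alpha$, $\alpha = 3$), and a
   shear-stress-driven remodeling stage (low-shear terminals are pruned, side
   branches sprout preferentially on high-shear perfused segments) runs until
   the capillary count plateaus.  An outer up-scaling loop subdivides the
   lattice and repeats growth, giving a hierarchy of vessel calibers.
2. **Hemodynamics.** Each segment is a Poiseuille resistor,
   $q = \pi r^4 \Delta p / (8 \eta l)$, with the blood viscosity
   $\eta = \eta_{plasma}\,\eta_{rel}(2r, H)$ from the Pries in-vivo law at a
   constant hematocrit $H = 0.45$.  Kirchhoff balance at the junctions gives a
   sparse symmetric linear system for the nodal pressures; boundary pressures
   at tree roots are prescribed as functions of the root radius.
3. **Tumor growth.** The tissue is a mixture of volume fractions (tumor
   cells, normal cells, necrotic debris, rigid ECM, interstitial fluid as the
   incompressibility remainder) sharing one velocity
   $v = -\mu \nabla p_{solid}$ with $p_{solid} = E(\phi - \phi_0)_+$.
   Proliferation is oxygen-gated and density-regulated so that it cancels
   apoptosis at the homeostatic fraction; necrosis transfers mass to the
   debris phase below an oxygen threshold.  A signed-distance level set
   $\theta$ (negative inside the tumor) tracks the interface.  The vessel
   network is remodeled in 1 h steps: growth-factor-directed sprouting with
   tip splitting, wall degeneration of tumor vessels, circumferential dilation
   up to a maximal radius, and stochastic collapse of degenerate low-shear
   vessels.
4. **Interstitial fluid and drug.** On a frozen tumor state the interstitial
   fluid pressure (IFP) solves
   $\nabla \cdot (K \nabla p) + Q(p) = 0$ with the Darcy conductivity $K$
   interpolated across the interface, Starling transvascular sources
   $\lambda_l (p_{blood} - p - \sigma(\pi_v - \pi_i))$ deposited from a uniform
   sampling of the vessel surfaces, and distributed lymphatic sinks
   $\lambda_L S_L (p - p_L)$ that are absent inside the tumor.  The drug
   model is two-compartment: the extracellular concentration $s_1$ (per fluid
   volume) is advected by the Darcy flux, diffuses, exchanges with cells
   ($\Gamma_{12} = \gamma(\phi_c)(k_{12} s_1 - k_{21} s_2)$) and with the
   vasculature and lymphatics; the intracellular concentration $s_2$ only
   exchanges.  Exposure is summarized per voxel by ICmax (maximum of $s_2$
   over time) and ICAUC (its time integral).

# Parameters

All constants live in `default_parameters()`, unit-consistent in
micrometres, seconds and kilopascals.  The choices that matter most:

* **Drug exchange rates.** The uptake/release ratio is fixed at
  $k_{12}/k_{21} = 100$, the steady-state intracellular-to-medium ratio
  observed for Doxorubicin in cell cultures.  The absolute scale (membrane
  permeabilities $k_{12} = 0.04$, $k_{21} = 4\times 10^{-4}$ um/s combined
  with the cell geometry factor
  $\gamma = \phi_c f A_{cell}/V_{cell}$) puts cellular uptake on the scale of
  minutes and release on the scale of hours, as observed.
* **Drug diffusivity.** $D_s = 16$ um$^2$/s in the interstitium, the
  experimental estimate for Doxorubicin in tumor tissue.  With the retention
  ratio of 100, the diffusion law $t = L^2 (k_{12}/k_{21}) / D_s$ gives a
  saturation time of roughly 1.7 thousand hours for $L = 1$ mm — far beyond
  any clinical infusion window, which is why prolonged infusions change the
  scale but not the shape of the exposure maps.
* **Wall permeabilities.** Hydraulic: leaky tumor capillary
  $\lambda_l^T = 1.4$, normal capillary $\lambda_l^N = 0.0225$
  um/(kPa s) (literature values for tumor and normal microvessels).  A
  vessel's permeability interpolates with wall maturity $w$: resistance is
  proportional to $w$, anchored at the normal value for the physiologically
  normal thickness $w_N(r) = 0.65\, r^{0.6}$ um and capped at the tumor value
  as $w \to 0$.  The diffusive drug permeabilities use the same interpolation
  with the tumor/normal ratio constrained to equal the hydraulic ratio.
* **Lymphatics.** A channel lattice with one vessel of 10 um radius every
  100 um yields the surface density $S_L = 0.0188$ per um;
  $\lambda_L$ matches the normal capillary wall; the lymphatic pressure is
  $-0.5$ kPa.  The tumor has no lymphatics in the base case (variation
  cases restore a fraction of them).
* **Osmosis.** Reflection coefficients 0.91 (normal) / 0.82 (tumor) with
  plasma and interstitial oncotic pressures 2.7 and 1.33 kPa.
* **Tissue.** Homeostatic cell fractions 0.6 (tumor) and 0.4 (normal), ECM
  fraction 0.2, relaxed fraction 0.3; proliferation once per day, normal-cell
  lifetime 10 days, hypoxic die-off within 48 h; oxygen thresholds 0.3
  (proliferation) and 0.03 (necrosis) on the blood-normalized scale; tumor
  oxygen consumption twice normal, tuned so the oxygen penetration depth in
  tumor tissue is about 100 um; the trans-wall oxygen permeability is
  calibrated so normal tissue sits above roughly half the blood level.
* **Root pressures.** The radius-to-pressure boundary curves are a logistic
  fit to microvascular pressure data (arterial rising toward systemic
  pressure with radius, venous falling toward central-venous pressure, the
  arterial curve strictly above the venous one); the parameter object records
  `root_pressure_model = "logistic-fallback"` so downstream consumers can see
  which curve family produced the boundary conditions.

`case_variation()` implements the studied departures from the base case as
multiplicative deltas: heavier drug particles (all diffusion-related
constants scaled by $(m/m_0)^{-1/3}$ with mass ratio 1000), prolonged
infusions (24 h / 96 h), convection switched off, the tumor wall-permeability
bound scaled by 10, 1/100 or 1/1000, tissue conductivity scaled by 10
together with $D_s$ and the lymphatic permeability, normal lymphatics scaled
by 10, and tumor lymphatics restored at 10% or 100% of the normal density.

# Numerics

* **Grids.** Scalars live on cell centers of a uniform staggered grid
  (spacing $h = 30$ um, two to three cell diameters), velocities and fluxes
  on faces.  Slab mode (`nz = 1`) shares the full 3D code path; the vessel
  lattice is FCC in 3D (12 neighbors, 60-degree branching angles) and its 2D
  analogue, the triangular lattice, in slab mode.  Segment geometry is
  derived from integer lattice indices, never stored.
* **Elliptic solves.** Diffusion operators are 7-point (5-point in slab)
  finite-volume stencils with harmonic face averaging, assembled sparse and
  solved directly (the problem sizes here factor in milliseconds); the
  residual is audited after every solve against a $10^{-8}$ relative bound.
  Oxygen and IFP use the same machinery, as do the analytic screened-Poisson
  checks in the test suite.
* **Surface coupling.** Vessel-wall exchange is deposited from a uniform
  random sampling of the cylindrical surfaces (default 0.015 samples per
  um$^2$, a fixed sub-seed per stage) through a multilinear cloud-in-cell
  kernel that partitions unity exactly — total deposited area converges to
  the true lateral area at the 1% level, and linearity of the Starling form
  in $p$ is kept so the source enters the sparse system implicitly.
* **Advection.** Volume fractions, the level set and the drug use
  conservative first-order upwind fluxes under a CFL bound of 0.8 (the
  phase update additionally respects the parabolic bound of the
  porous-medium-like cell motion, and the velocity is refreshed every
  sub-step so packing feedback is not lagged).  Time integration of the
  phases is the improved (Heun) Euler method; the drug splits operators into
  advection, diffusion, an *exact* closed-form update of the linear
  two-compartment exchange (mass-preserving to round-off), and an exact
  exponential update of the linear vascular/lymphatic exchange.
* **Level set.** Reinitialization is geometric: the zero contour is
  reconstructed from edge crossings by linear interpolation and $\theta$ is
  reset to the exact signed distance to that point set.  At desk-scale grid
  sizes this restores $|\nabla\theta| = 1$ essentially exactly and moves the
  contour by less than a tenth of a cell, which the suite asserts.
* **Randomness.** Every stochastic stage (root placement, growth, each
  remodeling rule, surface sampling) draws from a named sub-stream derived
  from the master seed (`derive_seed()`), so trajectories are bitwise
  reproducible and stages can be replayed independently.
* **Degenerate inputs.** Networks without a pressure boundary in some
  component, pure-Neumann elliptic systems without sinks, empty tumors and
  empty sampling sets all fail fast with named errors rather than returning
  silently wrong fields; fragments disconnected by vessel collapse are
  dropped (they can no longer exchange anything).

# The synthetic scenes and what they do (not) show

`make_fixture()` provides deterministic desk-scale scenes: a single perfused
vessel in a tissue block, an arteriovenous pair bridged by capillaries, a
homogeneous lymphatic slab, and a frozen spherical tumor (level-set sphere,
necrotic core, parallel vessels that are dilated and wall-degenerate inside
the tumor with a thinned central density).  The frozen tumor emulates the
late compartmentalized state — elevated plateau IFP, sharp boundary drop,
outward rim flow, fluid-absorbing interior vessels, exponential early drug
halos, stronger peripheral retention without convection — without running
the growth simulation.

These scenes reproduce the *mechanisms* and orderings of the full model, not
its full-scale magnitudes: quantitative figures such as the absolute mean
blood pressure or the extravasation fraction of order $10^{-4}$ emerge only
from large 3D hierarchies (millimetre domains, hundreds of hours of growth,
ensembles of runs), which exceed desk scale deliberately.  Desk runs here use
slab grids of 30-48 cells per side, construction lattices around 12x14 sites
with one up-scaling step, growth runs of a few hours of model time, and drug
windows of 2-12 h in the tests (the API default remains the 96 h observation
window).  The ensemble driver (`run_ensemble()`) fans seeds over any runner;
the published protocol of fifteen independent runs is a single call.

# Design choices made where the design was open

* The map from terminal shear stress to growth/removal probabilities is
  rank-based and bounded in [0.1, 0.9]: it preserves the "high shear grows"
  ordering without introducing unprinted constants, and equal stresses give
  exactly balanced dynamics.
* The capillary plateau criterion is a moving-average comparison (relative
  change below 1% over 50 sweeps at full scale; 5% over 20 sweeps in the
  desk preset).
* Remodeling attachment happens at nodes of high-shear segments (side
  branching near perfused paths) rather than by extending flowing terminals;
  extending a connected terminal would sever its capillary bridge and
  systematically destroy the interdigitation the stage is meant to create.
* Capillaries may bridge opposing terminals over one or two lattice bonds
  (through a free intermediate site); strict single-bond adjacency is too
  rare on coarse desk lattices to seed the remodeling stage.
* Collapse probability is parameterized by the unstable-vessel survival
  time: $p = \min(1, \Delta t / t_{surv})$, gated on zero wall maturity and
  sub-critical shear.
* Unperfused segments persist (flagged, exchanging nothing) during growth;
  fully disconnected fragments are removed.
* Domain boundaries: zero-flux for all continuum fields, with lymphatics
  anchoring the IFP far field; boundary faces carry no advective flux, so
  the box is closed and mass audits are exact.
* Drug entering lymphatics leaves the system (no recirculation), and the
  plasma concentration is spatially uniform over the network by
  construction.

# Known limitations

Vessels are straight lattice segments; branching angles are fixed at 60
degrees.  The advection schemes are first-order (monotone but diffusive), so
sharp fronts smear over a few cells.  Hematocrit is constant network-wide
(no phase separation at bifurcations).  The IFP does not feed back on the
vascular mass balance — justified by the smallness of the extravasated
fraction, which the package itself measures.  Pharmacodynamics (cell kill)
and saturable cellular binding compartments are out of scope, so late-time
intracellular concentrations are upper bounds.
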