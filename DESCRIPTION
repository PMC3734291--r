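Package: tumorperf
Title: Vascularized Tumor Growth, Interstitial Fluid Flow and Drug Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid discrete-continuum simulator of solid vascularized tumors at
    desk scale. Synthesizes hierarchical arteriovenous vessel networks on FCC or
    triangular lattices, computes Poiseuille/Kirchhoff blood flow with the Pries
    in-vivo viscosity law, remodels the vasculature stochastically during
    level-set tumor growth (sprouting, wall degeneration, dilation, collapse),
    solves the stationary interstitial fluid pressure and Darcy flow with
    Starling vessel sources and lymphatic sinks, and propagates a two-compartment
    (extracellular/intracellular) drug concentration with convection, diffusion
    and transmembrane exchange, reporting spatial exposure metrics (ICmax,
    ICAUC), radial profiles and region summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
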