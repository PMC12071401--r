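Package: crumbsim
Title: Coupled Multiphase Heat, Moisture and Deformation Simulator for Bread Baking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A finite-volume simulator of bread baking as a deforming multiphase
    porous medium. Tracks solid matrix, liquid water, water vapor, carbon dioxide
    and inert air on an axisymmetric (or reduced 1-D axial) grid with moving-mesh
    (ALE) columns; moisture phase change is modelled with an equilibrium closure in
    closed pores and a nonequilibrium rate law in open pores, heat transfer includes
    the evaporation-condensation-diffusion (ECD) enhancement of conductivity, gas
    flow follows a Darcy reduction of the pore momentum balance, and dough expansion
    is driven by closed-pore gauge pressure against a temperature-dependent
    viscosity. Includes constitutive state functions (pore opening, crusting,
    viscosity sigmoid), an oven-program generator, scenario configuration from YAML,
    parameter sweeps and diagnostics export (CSV, VTK, JSON).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
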