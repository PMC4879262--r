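Package: finturing
Title: Turing Patterning of Catshark Fin Skeletal Elements on Growing Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Bmp-Sox9-Wnt (BSW) linear Turing network, spatially
    modulated by an FGF gradient, on unstructured triangular meshes of growing
    catshark pectoral fin buds. Provides synthetic fin-bud outline generation
    and triangulation, conservative concentration remapping between growth
    stages, a finite-volume Heun reaction-diffusion integrator with
    multiplicative noise, linear stability analysis (dispersion relations and
    Turing-space scans), pattern quantification (spot/stripe classification,
    distal-distance and phase statistics), virtual fate mapping, and scripted
    in-silico perturbation experiments (Bmp, Wnt and Fgf inhibition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
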