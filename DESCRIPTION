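Package: poroedema
Title: Poroelastic Finite-Element Simulation of Inflammatory Myocardial Edema
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of inflammatory edema in cardiac tissue by
    coupling a reaction-diffusion-chemotaxis model of pathogen and leukocyte
    dynamics with interstitial fluid flow (Starling capillary filtration and
    Hill-type lymphatic drainage) and quasi-static linear poroelasticity on
    two-dimensional triangular meshes. Provides P1 finite-element assembly with
    SUPG stabilization for chemotactic transport, a synthetic curved-wall mesh
    generator and a Gmsh MSH reader, random lymph-vessel placement, isoline
    based quantification of the edematous area, parameter sweeps and
    seed-robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
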