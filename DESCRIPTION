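Package: carotidflow
Title: Hemodynamics of Idealized Carotid Bifurcations with Plaques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics for the carotid
    bifurcation. Builds parametric two-dimensional planar lumen geometries
    of the common, internal and external carotid arteries with a carotid
    bulb and smooth plaque protrusions at configurable sites, meshes them
    with graded boundary layers, and solves pulsatile incompressible flow
    with Carreau-Yasuda shear-thinning rheology on the resulting
    triangulations. Post-processing covers wall shear stress, TAWSS, OSI,
    ECAP, plaque risk stratification, cross-section velocity profiles,
    Lagrangian platelet-surrogate tracking with residence times, and
    suite-level statistics (Spearman correlations across bifurcation
    angles, non-parametric location tests across wall sites).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
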