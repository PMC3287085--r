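Package: coroflow
Title: Desk-Scale Hemodynamics of Plaques in an Idealized Left Coronary Bifurcation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates an idealized two-dimensional left coronary bifurcation
    (left main stem dividing into the left anterior descending and left
    circumflex branches), inserts raised-cosine plaques producing a prescribed
    percent diameter stenosis, meshes the lumen with a deterministic mapped
    triangulation, and solves transient laminar incompressible Navier-Stokes
    flow with a pulsatile Fourier-series inlet under Newtonian or generalized
    power law (shear-thinning) blood rheology. Post-processing computes wall
    shear stress, the local pressure-gradient magnitude, cross-sectional
    velocity profiles and recirculation fractions, and reduces a four-arm
    plaque/no-plaque by Newtonian/non-Newtonian study to summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
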