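Package: tpmscaffold
Title: Functionally Graded TPMS Bone-Scaffold Design, Morphometry and
    Voxel Homogenization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs porous bone-tissue-engineering scaffolds from nodal
    (trigonometric) triply periodic minimal surfaces (P, D, gyroid and
    tubular-gyroid units), fuses heterogeneous units into functionally
    graded structures with a sigmoid transition weight, extracts printable
    watertight STL meshes by isosurfacing sampled implicit fields, computes
    trabecular morphometry (porosity, trabecular thickness and separation,
    surface area density, structure model index) on binarized micro-CT-like
    volumes, maps image gray values to bone density and elastic modulus by
    the cancellous-bone power law, evaluates apparent elastic modulus and
    von Mises stress summaries with a matrix-free voxel hexahedral
    linear-elasticity solver, and tunes structural parameters to hit target
    porosity or stiffness. Includes analytic phantom generators so the
    whole pipeline is testable without external scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
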