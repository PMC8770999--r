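Package: mandfix
Title: Finite Element Comparison of Mandibular Angle-Fracture Fixation Techniques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale finite element pipeline for comparing single-plate
    (Champy) and biplanar miniplate fixation of mandibular angle fractures
    under physiological masticatory loading. Generates idealized U-arch
    mandible meshes with cortical, trabecular and tooth regions, a planar
    fracture gap and miniplate/screw hardware; assembles muscle forces from
    EMG x PCSA x specific tension and chewing-side condylar/bite boundary
    conditions; solves the static small-strain elastic problem on linear
    tetrahedra with tie constraints and compression-only frictional penalty
    contact; and computes interfragmentary displacement statistics, trimmed
    principal-strain extremes, sectional moment profiles and strain-difference
    maps against the unfractured control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
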