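Package: memprofiler
Title: Local Lipid-Packing Density Profiling for Membrane-Sensor Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analyses of how a transmembrane lipid-saturation
    sensor reads its bilayer environment. Computes voxelized lipid-atom
    number-density maps and composition difference maps from bilayer
    trajectories, standard bilayer descriptors (area per lipid, thickness,
    acyl-chain order parameters), rotational-state populations of
    transmembrane-helix dimers, membrane-probe spectroscopy reductions
    (C-Laurdan generalized polarization, ratiometric FRET, FCS
    autocorrelation fitting, cwEPR proximity index), and the acyl-chain
    molarity of liposome bilayers. Includes seeded synthetic-data
    generators for every input so the full pipeline is testable without
    external trajectories or spectra.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
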