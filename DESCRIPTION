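Package: tpmjunction
Title: Coiled-Coil Overlap Junction Geometry, Thermal Melts, and Radioligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the head-to-tail overlap junction of
    tropomyosin coiled coils and the integration of small molecules into it.
    Builds ideal coiled-coil backbones from Crick parameters, assembles
    chimeric overlap models by fragment superposition, measures per-residue
    coiled-coil radius and overlap bend/twist angles on structures and
    multi-model trajectories, performs range-restricted Kabsch superposition
    and RMSD, extracts melting temperatures from circular-dichroism thermal
    melts by Savitzky-Golay smoothing, differentiation and Gaussian peak
    fitting, and fits one-site radioligand binding isotherms with
    per-junction stoichiometry. Includes seeded synthetic-data generators
    with recorded ground truth for every input class.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
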