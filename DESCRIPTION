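Package: muellerprobe
Title: Virtual Six-Fibre Probe for 3x3 Mueller Matrix Tissue Polarimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational core of a flexible six-fibre polarimetric probe that
    measures the linear 3x3 Mueller matrix of distal tissue through micro-polariser
    terminated multimode fibres. Provides Stokes/Mueller algebra with full 4x4
    composition and reflection-geometry double passes, a virtual-probe forward
    model for the nine pair-labelled intensity measurements, system-matrix
    construction and inversion to recover the sample Mueller matrix,
    mirror-polariser calibration regression for the nine per-pair coupling
    coefficients, and a 3x3 polar decomposition into diattenuation, retardance
    and depolarisation with the physical-retardance correction for reflection
    geometry. Includes a synthetic tissue generator, CSV/JSON/YAML file formats
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
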