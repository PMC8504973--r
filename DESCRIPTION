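Package: mwcgate
Title: Three-State Allosteric Analysis of Pentameric Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of pentameric ligand-gated ion channel
    gating intermediates from joint steady-state fluorescence-quenching and
    electrophysiological pH-titration data. Implements a three-state
    (resting / pre-active / active) Monod-Wyman-Changeux model with two
    classes of five proton-binding sites, empirical Hill fitting with the
    field's normalization and rundown-correction conventions, a stepwise
    MWC fitting strategy yielding per-mutant isomerization-constant
    multiplication factors, a seeded synthetic titration-data generator for
    end-to-end parameter-recovery testing, and geometry metrics (twist
    angle, inter-subunit distances, pore ring radius, RMSD) on multi-model
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
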