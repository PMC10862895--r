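Package: switchscope
Title: Thermal, Kinetic, NMR and Trajectory Read-Outs for G-Protein
    Switch-Region Variants
Version: 0.1.0
Authors@R:
    person("switchscope", "developers", email = "switchscope@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for characterizing nucleotide-state
    phenotypes of G-protein alpha-subunit (Galpha) variants. Fits
    variable-temperature circular dichroism melts to the Boltzmann sigmoid and
    classifies thermal phenotypes against wild-type GDP/GTP references; fits
    tryptophan-fluorescence nucleotide-exchange traces to the one-phase
    association model; converts saturation-transfer difference (STD) NMR peak
    integrals into amplification factors with propagated errors and bins the
    normalized epitope fingerprint; post-processes coordinate trajectories into
    inter-switch hydrogen-bond occupancy matrices, per-residue backbone RMSF and
    nucleotide-proton closest-residue proximity profiles with replica
    aggregation. A seeded synthetic-data generator emulates the statistical
    structure of each input so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
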