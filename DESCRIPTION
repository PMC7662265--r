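Package: pepstruct
Title: Helicity, Interface Mapping and Ensemble Geometry for Model Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structural analysis of short model peptides studied
    by circular dichroism (CD) and solution NMR. Converts raw CD ellipticity
    to mean-residue molar ellipticity and estimates helix content from the
    222 nm band; computes secondary chemical shifts (delta-delta) of Halpha
    and Calpha nuclei against a random-coil reference, detects helical
    segments, and converts segment-averaged deviations into two-state helix
    populations with propagated errors; maps peptide-peptide interfaces with
    weighted chemical-shift perturbations and exports active-residue lists
    for data-driven docking; analyses multi-model coordinate ensembles
    (backbone superposition RMSD, helix-axis fitting, inter-helix angle
    statistics, Ramachandran summaries); and computes design-stage
    physicochemical properties (mass of terminally capped peptides, net
    charge, isoelectric point). A synthetic-data module generates two-state
    helix-coil shift tables, perturbed mixtures, two-basis CD spectra and
    hinged two-helix coordinate ensembles with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
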