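Package: rcexciton
Title: Fragment-Resolved Excited-State Analysis of Photosystem II Reaction Center Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing time-dependent density functional theory
    (TDDFT) excited states of multi-chromophore pigment-protein assemblies such
    as the Photosystem II reaction center. Molecular orbitals are decomposed
    into per-cofactor percentage contributions by Mulliken population analysis,
    excited states are assigned to the cofactor dominating their occupied
    orbitals, one-electron transitions are classified by the direction of
    charge transfer along the D1 (active) and D2 (inactive) pigment branches,
    charge-transfer extent is measured from the barycenters of density
    depletion and increment of the unrelaxed difference density, and
    Gaussian-broadened absorption spectra with Qy/Qx/Soret band reports and
    wild-type-versus-mutant band-shift comparisons are produced. Includes
    readers for a formatted-checkpoint subset and excitation logs, a lossless
    record container, and a synthetic-data generator with ground-truth
    sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
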