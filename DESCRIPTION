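Package: escapist
Title: Protein Model Quality Assessment from Electrostatic Potential
    Differences of Consecutive Sidechain Atoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Knowledge-based model quality assessment for protein
    structures using the electrostatic potential difference (EPD, in
    kT/e) between the Cbeta atoms of sequence-consecutive residues.
    Provides a learning phase that estimates per amino-acid-pair mean
    EPDs from a set of native structures, a PDscore that measures the
    normalized absolute deviation of a candidate model from those
    learned means, and decoy-set evaluation with native-versus-decoy
    specificity. Includes a built-in Coulomb / finite-difference
    Poisson electrostatics backend, an adapter for the external
    PDB2PQR+APBS toolchain, synthetic peptide and decoy generators for
    fully self-contained testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
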