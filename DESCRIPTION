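Package: noodiag
Title: Electron-Correlation Measures and Multireference Diagnostics from
    Natural Orbital Occupancies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes occupancy-based electron-correlation indices
    (nondynamic, dynamic and total correlation, their size-intensive
    forms, the occupied/virtual split and the maximal single-orbital
    contribution) from natural orbital occupation numbers, classifies
    molecules as single- or multireference against method-specific
    thresholds, and provides the analytic bridges to the leading
    configuration-interaction coefficient and to the Nielsen-Janssen D2
    doubles-amplitude diagnostic, including unrelaxed second-order
    density-matrix blocks.  Ships exact-diagonalization model systems
    (Hubbard dimer and chains, two-level pairing) as in-package oracles,
    readers for Molden, wfx, plain-text and JSON occupancy files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
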