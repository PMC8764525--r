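Package: qtykit
Title: QTY Design of Water-Soluble Variants of Alpha-Helical Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the QTY protein-solubilization code:
    deterministic QTY/NTY residue substitution within annotated transmembrane
    (TM) helices, sequence-based property profiling (molecular weight,
    isoelectric point, Kyte-Doolittle hydropathy, helix ratio, a pluggable
    sequence-based Tm index), change metrics for designs (R_ACT, R_SC),
    a directed combinatorial variant-library designer with in-silico
    solubility and helix-retention filtering, reverse translation and
    overlap-based DNA fragment design for gene synthesis, helical-wheel
    projections, structured design reports, and a synthetic multi-pass
    membrane-protein generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
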