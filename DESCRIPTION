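Package: confenum
Title: Exhaustive Enumeration of Disordered-Linker Conformations and
    Ensemble Population Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systematic enumeration of disordered protein linker
    conformations within NMR-derived backbone torsion boxes using an interval
    branch-and-prune tree search, reduction of large conformer sets with a
    periodic self-organizing map and its U-matrix, assembly of peptide
    fragments into full-length chains by overlap superposition, attachment of
    rigid folded domains by grid search and vector alignment, and
    determination of conformer populations by maximum-entropy reweighting
    against observable curves (small-angle scattering, paramagnetic
    relaxation enhancement, residual dipolar couplings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
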