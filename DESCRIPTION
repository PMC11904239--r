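Package: pfvmkit
Title: Single-Sequence Conformational Ensembles via a Protein Folding Shape Code
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts conformational ensembles of protein structures from a
    single amino-acid sequence. Backbone Cα traces are encoded into a
    27-letter protein folding shape code (PFSC); a pentamer fold-pattern
    database maps every five-residue sequence fragment to its observed local
    folds; a protein folding variation matrix (PFVM) lists the ranked fold
    variants at every sequence window and yields exact conformation counts;
    candidate conformation strings are scored and compared with a normalized
    protein folding structural alignment (PFSA); and Cα-trace ensemble models
    are assembled by fragment-level conformation-homology search against a
    PFSC-indexed structure library. Includes a synthetic-backbone fixture
    generator so the full pipeline runs without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
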