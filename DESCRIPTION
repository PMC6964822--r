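Package: ms2rules
Title: Substructure Recommendation for Tandem Mass Spectra by Association
    Rule Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines "spectral feature(s) => substructure" association rules
    from structure-annotated MS/MS spectral libraries, controls the false
    discovery rate of the mined rules with a target-decoy scheme based on
    rule recall, and uses the filtered rule database to recommend ranked
    (maximum common) substructures for unknown tandem mass spectra.
    Includes readers for MGF spectral libraries and fragmentation-tree
    edge tables, a bond-cleavage substructure generator, and a synthetic
    spectral-library simulator with planted feature-substructure
    associations for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
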