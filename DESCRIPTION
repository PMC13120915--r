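Package: flavatlas
Title: Network Pharmacology Mapping of Dietary Flavonoids to Therapeutic
    Drug Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a confidence-filtered master network of protein-protein
    and compound-protein interactions (STRING/STITCH-dialect link tables),
    scores flavonoid associations with ATC drug categories by an exact
    hypergeometric target-overlap test with joint Benjamini-Hochberg FDR
    control, translates the resulting association-strength matrix into
    food-level therapeutic predictions by Spearman rank correlation of
    flavonoid content profiles, and summarizes epidemiological-evidence
    support rates and bioassay concordance. Includes a seeded synthetic-data
    generator with planted ground truth so every stage of the pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
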