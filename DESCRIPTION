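Package: polysd
Title: Family-Based Mapping of Polygenic Sex Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping genetic sex determination in small fish
    families: marker-sex association with Fisher's exact test, dominant-model
    allele screening, per-family XY/ZW system classification with penetrance
    estimation, sex-ratio statistics, two-point linkage for chromosome-fusion
    detection, and reference-guided scaffold anchoring from window alignments.
    Includes a Mendelian pedigree simulator with multi-locus epistatic sex
    determination, incomplete penetrance, recombination under the Haldane map
    function, and read-depth-driven missingness, so every analysis stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
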