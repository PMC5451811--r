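Package: paleodur
Title: Habitat-Dependent Species Durations in the Fossil Record
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the relationship between inferred habitat
    type and species duration in fossil occurrence data, built around the
    amphibian fossil record. Reads Paleobiology-Database-flavoured
    occurrence tables, assigns occurrences to flow-energy habitat
    categories from lithology, computes stratigraphic durations and
    palaeo-grid range sizes, and provides the fossil-record quality
    metrics (FreqRat preservation probability, simple completeness
    metric, specimen completeness) and single-interval-taxon bias
    diagnostics needed to vet such data, together with robust
    group-comparison machinery (trimmed means, Kruskal-Wallis, pairwise
    Wilcoxon with false-discovery-rate correction, chi-square
    habitat-preference tests). A forward simulator of fossil records
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
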