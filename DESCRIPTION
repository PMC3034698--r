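Package: linkmapr
Title: Genetic Linkage Map Construction and Cross-Species Synteny Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic linkage maps from haploid, phase-known mapping
    populations (two-point linkage with independence LOD scores, linkage-group
    detection, incremental marker ordering with a three-point ripple, Kosambi
    map distances, chi-square segregation-distortion tests) and compares the
    resulting map against a second species' map through sequence-homology hits:
    linkage-group matching and composite detection, synteny-block and
    rearranged-block classification, and single- or double-marker insertion
    detection. Includes per-group and genome-wide map statistics with the
    chromosome-end length correction, map-saturation coverage estimates,
    anchor- and cytometry-based genome-size estimators, recombination rates,
    and a seeded simulator of rearranged genome pairs, haploid progeny and
    noisy homology tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
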