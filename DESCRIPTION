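Package: hhccdf
Title: Marker-Trait Association Scans with the Hierarchical Hypergeometric
    Complementary Cumulative Distribution Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scan association testing for categorical marker scores and
    a quantitative trait using the hierarchical hypergeometric complementary
    cumulative distribution function (HH-CCDF): genotype classes are stratified
    by ascending class phenotype mean, each of the n-1 categorical boundaries
    yields a hypergeometric upper-tail P value for the count of top-ranked
    observations falling in the higher-mean classes, and the per-boundary tails
    are combined by geometric mean. Companion methods (the hierarchical
    association coefficient and the one-way F test), min-max score
    normalization for cross-method overlays, delimited-table readers/writers,
    a command-line interface, and a triangle-pattern QTL-signal simulator for
    benchmarking signal-magnitude recovery are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
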