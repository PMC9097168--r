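Package: paleoqtl
Title: Brain cis-eQTL Analysis of Nearly Fixed Human-Derived Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating Homo sapiens-derived, nearly fixed alleles to
    cis-eQTL effects in brain tissues. Classifies variants against archaic
    hominin genotypes (Altai and Vindija Neanderthals, Denisovan) with
    coverage filters and ancestral-allele resolution, tests tissue and
    functional-category composition of derived high-frequency eQTLs with
    chi-square tests and adjusted residuals, performs greedy p-value-ordered
    LD clumping from haplotype r-squared, runs permutation tests for overlap
    with selective-sweep windows, tests regulatory directionality, and
    carries out two-sample Mendelian randomization (Wald ratio) with
    approximate-Bayes-factor colocalization. A synthetic-data generator
    emulates every input with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    ape,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
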