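Package: olivekin
Title: Kinship and Parentage Inference for Clonal Crops Typed with Codominant SSR Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying parent-offspring relationships among clonally
    propagated cultivars (such as olive) genotyped at multi-allelic codominant
    microsatellite and indel loci. Provides genotype table I/O (native and
    GenAlEx-style CSV), allele-frequency estimation, codominant genetic
    distances with neighbour-joining, UPGMA and Ward trees plus locus-bootstrap
    support, moment and maximum-likelihood pairwise relatedness estimators
    (including a reference-panel triadic mode) with bootstrap confidence
    intervals, six-class kinship categorisation, Mendelian trio/duo parentage
    tests with mutation tolerance, a diallelic sporophytic self-incompatibility
    model for paternity exclusion, and a pedigree simulator with stepwise
    mutation that supplies exact expected-relatedness ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
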