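Package: mppqtl
Title: Simulation and QTL Mapping Power Analysis for Multiparental
    Recombinant Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time simulation of experimentally evolved
    multiparental recombinant inbred line (RIL) panels modeled on the
    Caenorhabditis elegans multiparental experimental evolution design
    (16 founders, a funnel intercross, long mixed selfing/outcrossing
    evolution phases and RIL derivation by selfing), with
    domain-structured recombination, de novo mutation injection and
    full truth tracking of founder haplotype paths.  On simulated (or
    supplied) genotypes the package measures additive QTL detection
    power with a single-marker linear mixed model, two-locus epistasis
    power with a bootstrap-calibrated likelihood-ratio test, mapping
    resolution via LOD-drop/LD-ranked detection intervals, population
    structure (GRM, PCA, Hudson's Fst, haplotype entropy), effective
    numbers of tests by Ledoit-Wolf shrinkage eigendecomposition, and
    variant hard-filter and new-mutation summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
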