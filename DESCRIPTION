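Package: ernadens
Title: Somatic Mutation Density and Burden Profiling Around Enhancer RNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Profiles somatic single-base-substitution (SBS) density around
    enhancer RNA (eRNA) focal points and quantifies per-donor regional
    mutation burden. Collapses the 12 substitutions into the six
    pyrimidine-referenced categories while tracking the complementary form of
    each call, bins mutations in fixed-width windows around interval start,
    midpoint, and end anchors, normalises densities to MPKM (mutations per
    kilo total mutations per megabase), detects density peaks and dips
    against a Poisson background estimated from distant flanking sequence,
    tests transcriptional strand bias between complementary forms with a
    Wilcoxon signed-rank test under Benjamini-Hochberg control, and computes
    per-donor per-category MPKM burden over arbitrary BED-defined regions.
    Ships a synthetic-cohort generator (reference chromosomes, eRNA
    intervals, per-donor SBS catalogs with configurable spectra, positional
    intensity, and strand asymmetry) so the whole pipeline is testable
    without access to controlled somatic-mutation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    readr,
    rlang,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
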