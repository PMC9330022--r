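Package: plastisweep
Title: Reciprocal-Transplant Expression Plasticity Screens and Two-Population Selective-Sweep Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two analyses of a highland/lowland reciprocal-transplant
    experiment. The transcriptome half normalizes small-RNA count matrices (TMM and
    counts-per-million), tests pairwise group contrasts with a common-dispersion
    negative-binomial exact test, screens for environment-driven miRNAs (ENMs) by
    intersecting the environment-bearing ("effective") comparisons while excluding the
    same-environment ("ineffective") ones, and confirms candidates with a balanced
    two-way breed-by-environment ANOVA. The genome half computes windowed
    Weir-Cockerham Fst and per-population nucleotide diversity over sliding windows,
    calls candidate sweep regions above an Fst threshold, and annotates them with gene
    intervals. A synthetic-data module simulates negative-binomial count matrices and
    two-population diploid genotypes with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
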