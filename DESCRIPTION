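Package: ctcCGH
Title: Copy-Number Profiling of Rare Sorted Tumor Cells from BAC Array CGH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of genome-wide BAC array comparative
    genomic hybridization (aCGH) profiles of rare, flow-sorted tumor cells
    such as circulating tumor cells. Provides a spot-level log2-ratio
    simulator with tumor-purity attenuation and sex-mismatch hybridization
    effects, triplicate-spot summarization with SD-based clone quality
    control, rank-based circular binary segmentation with permutation
    significance, five-state copy-number calling with an X-chromosome
    baseline adjustment for male-versus-female hybridizations, cohort
    recurrence frequencies, and a spatially weighted Pearson statistic for
    profile concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
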