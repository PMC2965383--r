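Package: lowpass
Title: Haplotype-Informed Genotype Calling and Selection Scans for
    Low-Coverage Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for refining diploid genotype calls from low-coverage
    short-read pileups using phased reference haplotype panels. Computes
    per-site genotype likelihoods from Phred-scaled base qualities,
    derives genotype priors from a haplotype-copying (hidden mosaic)
    model or from panel genotype frequencies, and combines prior and
    read evidence into Bayesian posterior calls. Includes read
    downsampling and accuracy-versus-depth evaluation, a sliding-window
    Tajima's D selection scan with outlier-region merging, per-gene
    averaging and paralog duplication-age stratification, and
    prioritization of novel variants by proximity and flanking
    linkage-disequilibrium evidence around disease-associated markers.
    A self-contained simulator generates LD-structured panels, mosaic
    diploid targets, pileups, array-like truth subsets and annotation
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
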