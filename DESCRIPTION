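Package: clinepool
Title: Clinal Pool-Seq Population Genomics Along a Lake-Stream Gradient
Version: 0.1.0
Authors@R:
    person("Misty", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pooled whole-genome sequencing data sampled
    along a fine-scale geographic gradient, motivated by parapatric lake-stream
    stickleback ecotype pairs. Provides SNP discovery from per-site nucleotide
    count tables, allele-frequency differentiation statistics (AFD, Fst),
    marker-panel ascertainment, maximum-likelihood geographic cline fitting
    (tanh cline with exponential tails), chromosome-center-biased
    differentiation (CCBD), high-differentiation-window scans benchmarked
    against haploid drift simulations, an individual-based diploid
    stepping-stone simulator of polygenic divergence with gene flow, and a
    mixture/ABC analysis of a transient admixture pulse. A synthetic-data
    generator with known ground truth emulates the sampling design so the
    whole pipeline is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
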