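Package: methylIsing
Title: Ising-Model Based Information-Theoretic Analysis of WGBS Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models whole-genome bisulfite sequencing (WGBS) methylation
    within 3-kb genomic regions by an inhomogeneous one-dimensional Ising
    joint distribution parameterized by five region-level parameters, and
    estimates those parameters by maximum marginal likelihood from
    incomplete reads. Provides exact transfer-matrix computation of
    partition functions, marginals, methylation-level distributions and
    samples; per-genomic-unit summaries of methylation level (MML) and
    normalized methylation entropy (NME); Jensen-Shannon distance (JSD)
    based differential analysis and detection of differentially methylated
    regions with empirical or logit-normal mixture nulls and
    Benjamini-Yekutieli FDR control; promoter/gene ranking by epigenetic
    discordance; and a WGBS read simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
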