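Package: cnakit
Title: Purity-Corrected Somatic Copy-Number Analysis, Cohort Covariate
    Normalization, Immune Signature Enrichment, and CRISPR Amplicon Indel
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cohort-scale somatic copy-number alteration (CNA)
    analysis in tumors: tumor-purity correction of segmented log2 copy
    ratios, gene-level and arm-level CNA calling on a triploid baseline,
    fraction of genome altered and aneuploidy terciles, an iterative
    cohort covariate-normalization algorithm (C-Norm) that equalizes
    arm-level CNA frequencies between sample groups by randomized masking
    of covariate-enriched samples, hypergeometric co-occurrence tests for
    genomic lesions, preranked weighted gene-set enrichment with
    immune-cell signatures, and an anchor-and-extend aligner for indel
    quantification in CRISPR amplicon sequencing. A synthetic-data module
    generates every input with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
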