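Package: corecruit
Title: Genome-Wide Inference of Co-Repressor Recruitment from Occupancy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring how a non-DNA-binding transcriptional
    co-repressor (such as yeast Tup1-Ssn6) is targeted across a genome.
    Implements sliding-window peak calling of ChIP-chip occupancy profiles
    with a Gaussian background null and false-discovery-rate control,
    co-occupancy analysis of co-repressor targets against candidate
    DNA-binding cofactors, a five-test composite percentile-rank screen that
    ranks transcription factors as candidate recruiters (motif
    over-representation, sensitivity, specificity, and top-quartile binding
    and expression correlations), and a cross-validated multiple-regression
    model that predicts co-repressor occupancy from recruiter occupancy with
    Gaussian imputation of missing array measurements. A synthetic-data
    generator with stored ground truth makes every stage testable without
    external microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
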