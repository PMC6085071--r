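Package: srnasig
Title: Small RNA Defence Signature Profiling and Pooled Prevalence Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles and classifies the small-RNA signatures that distinguish
    antiviral RNAi (viRNA), primary and ping-pong piRNA, and degradation
    responses on metagenomic contigs. Provides a seeded simulator of small-RNA
    libraries (Dicer siRNA duplexes, primary piRNAs, ping-pong secondary
    piRNAs, degradation fragments and miRNAs, with periodate-oxidation and
    polyphosphatase treatment effects and negative-binomial stranded RNA-seq
    counts), an ungapped mismatch-tolerant hierarchical read mapper, per-contig
    size/5'-base/coverage/ping-pong statistics with sequence logos, strand-bias
    binomial likelihood-ratio confidence intervals for replication and
    endogenous-viral-element assessment, quadrant classification of contigs,
    and maximum-likelihood prevalence estimation from pooled presence/absence
    assays with 2-log-likelihood support intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
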