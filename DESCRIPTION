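Package: famsel
Title: Two-Timescale Selection Analysis of Gene Families in Multi-Population Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting natural selection acting on
    large gene families (chemoreceptors, odorant-binding proteins and other
    multigene families) at two timescales. Between species it builds
    McDonald-Kreitman tables, computes the direction of selection (DoS)
    statistic, and estimates the fraction of adaptive amino-acid substitutions
    (alpha) and its synonymous-scaled rate (omega_a) by maximum likelihood
    over gene families. Within species it scans per-SNP Weir-Cockerham Fst
    across population pairs, calls empirical-tail outliers and family
    enrichment, computes unfolded site-frequency spectra and Fay and Wu's H
    with bootstrap confidence intervals, and assesses significance against a
    built-in neutral coalescent simulator supporting multi-population
    demography, migration, recombination and fixed-S conditioning. Relaxed
    constraint is summarised through replacement/silent diversity ratios,
    copy-number-variant gene-structure classification (complete duplications,
    chimeras, tandem fusions, deletions) and polymorphic null-allele
    summaries; receptor tuning breadth (lifetime kurtosis) is related to
    gene-level differentiation. A synthetic-data generator emulates an
    inbred-line diversity panel with known ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
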