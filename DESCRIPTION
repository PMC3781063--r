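Package: mcoamap
Title: Exclusion Mapping of Candidate Variants for Incomplete-Dominance Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing causal variants inside an identity-by-descent
    (IBD) candidate interval when a trait segregates with incomplete dominance,
    modelled on the exclusion mapping of the equine Multiple Congenital Ocular
    Anomalies (MCOA) / Silver locus. Provides site quality and depth filtering of
    VCF variant calls, conservation (constraint-element) and molecular-consequence
    annotation from a minimal gene model, exact genotype-concordance filtering
    across case / intermediate / control classes, IBD-interval narrowing from
    haplotype-discordant flanking markers, EM haplotype-frequency estimation with
    D, D' and r-squared for two-locus validation cohorts, and a case-versus-control
    relative read-depth scan for copy-number differences. A seeded synthetic-data
    generator plants ground truth (causal SNP pair, flank discordance clusters,
    reference-only sites, copy-number events) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
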