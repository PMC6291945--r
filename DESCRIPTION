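Package: consensnp
Title: Multi-Caller Consensus SNP Genotyping, Validation and Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-calling toolkit for SNP discovery from several variant
    callers run over one sample set. Combines per-caller VCFs into strict
    k-of-n intersections and per-individual consensus genotype sets, applies
    a filter cascade (biallelic SNPs, site quality, intra-specific
    polymorphism, missing-genotype modalities), validates genotype calls
    against an array truth set and across repeated experiments, and computes
    downstream genetic summaries: minor allele frequencies, windowed SNP
    density and its correlation with gene expression, gene-model annotation
    with coding-effect classification, and identity-by-state hierarchical
    clustering. Includes a fully seeded synthetic multi-caller data
    generator with structured populations so every pipeline stage can be
    tested against analytic expectations at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    ape,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
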