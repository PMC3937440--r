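Package: dga
Title: Disease-Gene Architecture: Gene Length, Mutation Rate and Diversity
Version: 0.1.0
Authors@R: person("DGA", "Maintainers", email = "dga@example.org", role = c("aut", "cre"))
Description: Analysis pipeline asking whether Mendelian-disease and GWAS genes
    differ from non-disease genes in gene length, per-site mutation rate
    (CpG-stratified human-chimp intron divergence), intronic genetic diversity
    and genealogy length. Includes CpG/non-CpG intron divergence counting,
    weighted non-synonymous mutational-opportunity enumeration over the
    standard genetic code, SNP-density and folded minor-allele-frequency
    summaries, a covariate-residualized group-comparison battery with
    standardized multiple regressions, and a calibrated synthetic gene-cohort
    generator so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
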