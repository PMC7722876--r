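Package: lineagetruth
Title: Lineage-Validated Somatic Truth Sets for Benchmarking Variant Callers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs validated somatic truth sets from multi-sample
    variant calls on a known cell lineage tree. Sites are filtered by
    genotype quality, no-call status and a ploidy-aware binomial
    allele-balance test, then classified by concordance with the clades of
    the lineage tree into germline, leaf and branch variants. For any
    ordered tumor / mixed-in-normal assignment the package assembles the
    positive somatic variants and a high-confidence region (callable genome
    minus leaf-variant and discordant copy-number exclusions), plans
    in-silico tumor-normal mixtures at chosen purities, and scores a
    somatic caller's VCF against the truth with exact Clopper-Pearson
    sensitivity intervals and asymptotic false-positive-rate intervals. A
    seeded simulator generates complete lineage-sequencing experiments
    (tree, joint genotypes, per-pair somatic calls, copy-number segments,
    ground-truth labels) so the whole pipeline can be exercised without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
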