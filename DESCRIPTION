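Package: genecentric
Title: Gene-Centric Burden Association and Evidence Integration for
    Cancer Predisposition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-level case/control association from variant
    functional-effect scores under dominant and recessive damage models,
    together with the surrounding gene-centric workflow: coherence filtering
    of GWAS summary statistics, genomic-inflation and collinearity QC,
    95% credible-set construction from fine-mapping posteriors, cross-cohort
    harmonization and concordance of summary statistics, and rule-based
    integration of multi-source gene evidence into a high-confidence core
    gene list. Includes a synthetic-cohort generator with founder-drift
    allele frequencies and planted dominant/recessive risk genes so the
    whole pipeline is testable without access to controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
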