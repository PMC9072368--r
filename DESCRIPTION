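Package: m5Cquant
Title: Quantitative mRNA m5C Mapping from RNA Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calls and quantifies 5-methylcytosine (m5C) sites in mRNA from
    RNA bisulfite sequencing data using a noise-aware filter cascade:
    high-quality base tallies, Gini-coefficient-guided removal of poorly
    converted reads (the C-cutoff filter), signal-ratio and
    conversion-resistant-gene checks, gene-specific binomial tests, and
    Stouffer combination across replicates. Downstream analyses classify
    sites into NSUN2-type (Type I) and NSUN6-type (Type II) motif classes,
    compute metagene density and GC profiles over proportional
    5'UTR/CDS/3'UTR bins, assess cross-species conservation of individual
    sites through ortholog position maps, profile base-pairing around sites
    with a bootstrap comparison test, and model methylation gain and loss
    with a logistic GLM over sequence and structure features. A synthetic
    data generator with planted truth (transcriptomes, bisulfite reads,
    species pairs, substrate pools) supports end-to-end validation, and a
    maximum-base-pairing dynamic program supplies secondary structures when
    none are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    Rsamtools,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
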