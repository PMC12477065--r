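Package: proteovar
Title: Proteogenomic Detection of Variant Peptides and Heterogeneity
    Analysis in Multi-Metastasis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds cohort-wide variant protein sequence databases from
    per-sample small-variant calls on coding transcripts, identifies and
    filters non-reference peptides (NRPs) from peptide-spectrum-match
    tables with isoleucine/leucine ambiguity handling, annotates single
    amino acid variants with reference-population allele frequencies and
    deleteriousness scores, and provides the downstream heterogeneity and
    survival statistics used in multi-metastasis proteogenomics: label-free
    abundance matrix post-processing with left-censored imputation,
    consensus clustering with partitioning around medoids, differential
    abundance, one-sided Fisher enrichment of NRP presence, pre-ranked gene
    set enrichment analysis, and Kaplan-Meier/Cox survival modelling. A
    fully synthetic multi-patient, multi-metastasis cohort generator with
    known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    digest,
    fgsea,
    stats,
    survival,
    utils,
    vcfR
Suggests:
    jsonlite,
    mclust,
    openssl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
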