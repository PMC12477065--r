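# proteovar

Proteogenomic detection of variant peptides and heterogeneity analysis in
multi-metastasis tumour cohorts.

## The problem

When RNA-seq and mass-spectrometry proteomics are collected from the same
tumour samples, variants called in the transcriptome predict protein
sequences that differ from the reference proteome. Peptides matching those
predicted variant proteins — but no reference protein — are direct evidence
that a sequence variant is translated. `proteovar` implements this
proteogenomic chain for cohorts of patients with multiple metastases, plus
the downstream statistics used to characterise inter- and intra-patient
heterogeneity and its survival implications:

1. **Variant protein database construction.** Small variants on coding
   transcripts are classified as in-frame or frameshift by the allele
   length rule (|Δlen| mod 3). All combinations of in-frame variants within
   a 30-amino-acid window are applied and translated (frameshifts are
   applied singly and translated to the first downstream stop); genes
   producing more than 10 000 combinations in a sample are dropped. The
   cohort-wide database is deduplicated by replacing FASTA headers with the
   MD5 digest of each sequence, with a provenance table (sample, prediction
   type, original header, MD5) mapping peptides back to their evidence.
2. **Non-reference peptide (NRP) calling.** Peptide-spectrum matches are
   filtered at 1% FDR and an external validation flag; peptides are
   compared I/L-collapsed (isoleucine and leucine are isobaric in MS), and
   any peptide occurring as a substring of the collapsed reference proteome
   is removed. Survivors are mapped cohort-wide against the variant
   database; peptides matching more than one gene are discarded; entries
   differing only by missed tryptic cleavages are merged; binary
   NRP-by-sample presence matrices are built and filtered to NRPs seen in
   at least three patients.
3. **Variant statistics.** NRP-supported variants are classified by
   reference-population allele frequency — absent ⇒ *novel*, > 1% ⇒
   *frequent*, (0, 1%] ⇒ *removed* — and genes are tested for an excess of
   novel over frequent mutations with a one-sided exact binomial test
   against the pooled reference ratio (BH-corrected). Deleteriousness
   scores supplied per genomic mapping are averaged; mean scaled C-score
   ≥ 20 flags a variant as potentially deleterious.
4. **Quantitative matrix preparation.** Label-free intensities are
   log2-transformed; values with log2 intensity < 10 are treated as
   artifacts; each replicate is median-centred and shifted to the global
   median; replicates are averaged; proteins with ≤ 10% missing values are
   retained and the rest of the missingness is imputed with a stochastic
   minimal-value (left-censored) model (q = 0.02, tune.sigma = 1). RNA-seq
   helpers implement the three-metric quality classifier, replicate
   selection, RPKM/TPM, and the counts > 9 in ≥ 30% of samples filter.
5. **Heterogeneity statistics.** Consensus clustering (resampled
   partitioning-around-medoids on Pearson distance, delta-area k
   selection), per-protein Welch differential abundance with BH correction,
   cluster-specific upregulation (positive effect and adjusted p < 0.05 in
   every pairwise contrast), one-sided Fisher enrichment of NRP presence,
   pre-ranked GSEA (weighted running-sum ES, gene-label permutation,
   NES = ES / mean |same-sign permuted ES|), gene-wise protein–RNA Spearman
   correlation, and Jaccard/Pearson sample similarity.
6. **Survival.** Kaplan–Meier with Greenwood intervals, log-rank tests,
   Cox proportional hazards (Breslow ties), per-protein survival ranking by
   signed Wald z after collapsing metastases to patient means (positive ⇒
   higher abundance in patients with shorter overall survival), survival
   GSEA on that ranking, single-sample signature scores, and
   majority-cluster patient classification (strictly more than 50% of a
   patient's metastases in the target clusters).

A synthetic cohort generator (`synth_config()` / `simulate_cohort()`)
produces a full multi-patient, multi-metastasis cohort — coding
transcripts, planted variants with known allele-frequency classes,
per-sample PSM tables, a block-structured abundance matrix with MNAR
missingness, and cluster-linked survival — with known ground truth, so the
entire pipeline is testable without any external data.

## Worked example

```r
library(proteovar)

cfg <- synth_config(n_patients = 8, metastases_per_patient = c(1, 4),
                    n_genes = 30, n_snv = 40, n_inframe_indel = 10,
                    n_frameshift_indel = 10, seed = 7)
cohort <- simulate_cohort(cfg)
cohort
#> synthetic cohort: 8 patients, 25 metastases, 30 genes, 60 planted variants

variants <- merge(cohort$planted$carriers, cohort$planted$variants,
                  by = "variant_id")
records <- do.call(rbind, lapply(split(variants, variants$sample_id),
  function(sv) predict_variant_proteins(cohort$reference$transcripts, sv)$records))
db <- build_cohort_db(records)
db
#> cohort variant db: 51 unique sequences, 146 provenance rows, 25 samples

patient_map <- setNames(cohort$samples$patient_id, cohort$samples$sample_id)
nrps <- nrp_call(cohort$psms, cohort$reference$proteome, db,
                 cohort$samples$sample_id, patient_map)
head(nrps$catalog[c("key", "gene_id", "variant_class", "n_patients")], 5)
#>                              key gene_id variant_class n_patients
#> 1                        TQLARFR    g001      in_frame          1
#> 2                  YEDEVLQDTWSYR    g001      in_frame          1
#> 3     CYYGLAQLLMCTTPSLLGENAALFLL    g003      in_frame          4
#> 4 EGSAWLCFVNLPVFETLNYGEASFVGTLLK    g003      in_frame          3
#> 5                       LPQRQLPR    g003    frameshift          3

assoc <- filter_min_patients(nrps$presence, min_patients = 3)
nrow(assoc$matrix)
#> [1] 9
summarize_catalog(nrps$catalog)$by_breadth
#>  1-2 patients  3-5 patients 6-10 patients  >10 patients
#>            44             9             0             0
```

The 60 planted variants give 51 unique variant protein sequences after
MD5 deduplication (146 provenance rows across the 25 metastases). NRP
calling recovers 53 validated non-reference peptides, each tied to a
single gene with its frame class; most are private to one or two patients
and 9 are broad enough (≥ 3 patients) for association analyses — the same
breadth skew the method produces on real cohorts.

Downstream, `consensus_cluster()` recovers planted proteomic clusters from
the prepared abundance matrix, `preranked_gsea()` on
`rank_genes_by_survival()` output links pathway blocks to overall
survival, and `km_estimate()` / `logrank_test()` / `cox_fit()` cover the
clinical endpoints. See the methods vignette
(`vignettes/proteogenomic-heterogeneity.Rmd`) for the modelling details
and design decisions.

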