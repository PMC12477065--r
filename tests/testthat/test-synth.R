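test_that("generation is deterministic and structurally valid", {
  cfg <- synth_config(n_patients = 4, metastases_per_patient = c(1, 3),
                      n_genes = 12, n_snv = 10, n_inframe_indel = 4,
                      n_frameshift_indel = 4, seed = 31)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  # byte-identical FASTA under the same seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(r1$proteome, f1); write_fasta(r2$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))

  # translation contract: start M, no internal stops, CDS length rule
  expect_true(all(substr(r1$proteome, 1, 1) == "M"))
  expect_false(any(grepl("*", r1$proteome, fixed = TRUE)))
  expect_true(all(nchar(r1$transcripts$cds_seq) %% 3 == 0))
  expect_equal(nchar(r1$transcripts$cds_seq),
               (nchar(r1$proteome) + 1) * 3, ignore_attr = TRUE)

  # gene sets partition all genes
  expect_setequal(unlist(r1$gene_sets), unique(r1$transcripts$gene_id))
  expect_equal(anyDuplicated(unlist(r1$gene_sets)), 0)

  expect_error(synth_config(cds_length_range = c(300, 901)),
               "configuration error")
  expect_error(synth_config(n_clusters = 1), "n_clusters")
  expect_error(synth_config(missing_frac = 1.2), "fractions")
})

test_that("gene-set union tracks the configured gene count", {
  cfg <- synth_config(n_genes = 50, n_snv = 5, n_inframe_indel = 2,
                      n_frameshift_indel = 2, seed = 32)
  ref <- generate_reference(cfg)
  expect_length(unique(unlist(ref$gene_sets)), 50)
})

test_that("planted variants follow the frame and AF rules", {
  co <- test_cohort()
  v <- co$planted$variants
  d <- abs(nchar(v$alt_allele) - nchar(v$ref_allele))
  expect_equal(v$frame_effect == "in_frame", d %% 3 == 0)
  # an indel with |len difference| = 3 is in-frame
  idx <- which(d == 3)
  expect_true(all(v$frame_effect[idx] == "in_frame"))
  # AF class consistency, including the frequent rule for af > 1%
  expect_equal(v$af_class, classify_af(v$af))
  expect_true(all(v$af_class[!is.na(v$af) & v$af > 0.01] == "frequent"))
  # every ref allele matches its transcript CDS
  tx <- co$reference$transcripts
  for (i in sample(nrow(v), 20)) {
    cds <- tx$cds_seq[tx$transcript_id == v$transcript_id[i]]
    expect_equal(substr(cds, v$pos[i] + 1, v$pos[i] + nchar(v$ref_allele[i])),
                 v$ref_allele[i])
  }
})

test_that("perfect concordance shares every patient variant across metastases", {
  cfg <- synth_config(n_patients = 4, metastases_per_patient = c(2, 4),
                      n_genes = 12, n_snv = 12, n_inframe_indel = 4,
                      n_frameshift_indel = 4, concordance = 1, seed = 33)
  ref <- generate_reference(cfg)
  samples <- proteovar:::make_samples(cfg)
  pl <- plant_variants(ref, samples, cfg)
  by_var <- split(pl$carriers$sample_id, pl$carriers$variant_id)
  for (vid in names(by_var)) {
    pats <- unique(samples$patient_id[samples$sample_id %in% by_var[[vid]]])
    expected <- samples$sample_id[samples$patient_id %in% pats]
    expect_setequal(by_var[[vid]], expected)
  }
})

test_that("observable data honours missingness, PSM and ground-truth contracts", {
  co <- test_cohort()
  # every planted NRP peptide appears in >= 1 PSM row of its sample
  pbs <- co$planted_peptides_by_sample
  hit <- mapply(function(s, p) {
    any(co$psms$sample_id == s & co$psms$peptide == p)
  }, pbs$sample_id, pbs$peptide)
  expect_true(all(hit))
  # planted peptides are absent from the I/L-collapsed reference
  hay <- paste(collapse_il(unname(co$reference$proteome)), collapse = "#")
  inref <- vapply(collapse_il(unique(co$planted_peptides$peptide)),
                  function(p) grepl(p, hay, fixed = TRUE), logical(1))
  expect_false(any(inref))
  # PSM q-values within the FDR convention
  expect_true(all(co$psms$q_value <= 0.01 + 1e-12))

  # missing_frac = 0 gives a complete matrix
  cfg0 <- synth_config(n_patients = 3, metastases_per_patient = c(1, 2),
                       n_genes = 10, n_snv = 4, n_inframe_indel = 2,
                       n_frameshift_indel = 2, missing_frac = 0, seed = 34)
  co0 <- simulate_cohort(cfg0, with_proteogenomics = FALSE)
  expect_false(anyNA(co0$abundance_raw))
  # overall missingness tracks the configured fraction
  expect_lt(abs(mean(is.na(co$abundance_raw)) - co$config$missing_frac), 0.03)
})

test_that("whole cohorts and their on-disk form are reproducible", {
  cfg <- synth_config(n_patients = 3, metastases_per_patient = c(1, 2),
                      n_genes = 10, n_snv = 6, n_inframe_indel = 2,
                      n_frameshift_indel = 2, seed = 35)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # VCF round trip through the standard parser
  s1 <- c1$samples$sample_id[1]
  vcf <- read_vcf(file.path(d1, sprintf("variants.%s.vcf", s1)),
                  sample_id = s1)
  planted <- merge(c1$planted$carriers, c1$planted$variants, by = "variant_id")
  planted <- planted[planted$sample_id == s1, ]
  expect_setequal(vcf$variant_id, planted$variant_id)
  i <- match(vcf$variant_id, planted$variant_id)
  expect_equal(vcf$pos, planted$pos[i])
  expect_equal(vcf$ref_allele, planted$ref_allele[i])
})

test_that("cluster-linked hazards order the Kaplan-Meier medians", {
  ok <- vapply(1:100, function(s) {
    cfg <- synth_config(n_patients = 40, metastases_per_patient = c(1, 3),
                        n_genes = 8, n_snv = 4, n_inframe_indel = 2,
                        n_frameshift_indel = 2, seed = 1000 + s,
                        survival_hazard_ratio_per_cluster = c(3, 1, 3, 1))
    co <- simulate_cohort(cfg, with_proteogenomics = FALSE)
    cl_by_pat <- split(co$true_clusters[co$samples$sample_id],
                       co$samples$patient_id)
    high <- vapply(cl_by_pat, function(cl) mean(cl %in% c(1, 3)) > 0.5,
                   logical(1))
    surv <- co$survival[match(names(cl_by_pat), co$survival$patient_id), ]
    if (sum(high) < 5 || sum(!high) < 5) return(NA)
    m_hi <- km_estimate(surv$time[high], surv$event[high])$median
    m_lo <- km_estimate(surv$time[!high], surv$event[!high])$median
    if (is.na(m_hi) || is.na(m_lo)) return(NA)
    m_hi < m_lo
  }, logical(1))
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("an unseparated cohort gives chance-level clustering", {
  ari <- vapply(1:20, function(s) {
    cfg <- synth_config(n_patients = 6, metastases_per_patient = c(2, 4),
                        n_genes = 24, n_snv = 4, n_inframe_indel = 2,
                        n_frameshift_indel = 2, cluster_effect_size = 0,
                        missing_frac = 0, seed = 2000 + s)
    co <- simulate_cohort(cfg, with_proteogenomics = FALSE)
    m <- log2(co$abundance_raw)
    m <- sapply(split(colnames(m), unname(co$replicate_map[colnames(m)])),
                function(cols) rowMeans(m[, cols, drop = FALSE]))
    cl <- pam_cluster(pearson_dist(m), 4)$assignments
    adjusted_rand(cl, co$true_clusters[colnames(m)])
  }, numeric(1))
  expect_lt(mean(ari), 0.2)
})
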