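# Shared small synthetic cohort and its variant database, built once per
# test run.

.test_cache <- new.env()

test_cohort <- function() {
  if (is.null(.test_cache$co)) {
    cfg <- synth_config(n_patients = 8, metastases_per_patient = c(1, 4),
                        n_genes = 30, n_snv = 40, n_inframe_indel = 10,
                        n_frameshift_indel = 10, seed = 7)
    .test_cache$co <- simulate_cohort(cfg)
  }
  .test_cache$co
}

test_cohort_db <- function() {
  if (is.null(.test_cache$db)) {
    co <- test_cohort()
    .test_cache$db <- cohort_db_from_cohort(co)
  }
  .test_cache$db
}

cohort_db_from_cohort <- function(co) {
  v <- merge(co$planted$carriers, co$planted$variants, by = "variant_id")
  recs <- do.call(rbind, lapply(split(v, v$sample_id), function(sv) {
    suppressWarnings(
      predict_variant_proteins(co$reference$transcripts, sv)$records)
  }))
  build_cohort_db(recs)
}

patient_map_of <- function(co) {
  stats::setNames(co$samples$patient_id, co$samples$sample_id)
}
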