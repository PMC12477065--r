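test_that("I/L collapse is total, idempotent and validated", {
  expect_equal(collapse_il("PEPTIDE"), "PEPTLDE")
  expect_equal(collapse_il("ILLI"), "LLLL")
  x <- c("MILK", "KAIIR")
  expect_equal(collapse_il(collapse_il(x)), collapse_il(x))
  expect_error(collapse_il("PEPTIDEZ"), "non-amino-acid")
  expect_error(collapse_il("PEP TIDE"), "non-amino-acid")
})

test_that("tryptic digestion cleaves after K/R except before P", {
  p0 <- digest_params(0, min_len = 1, max_len = 100)
  expect_setequal(digest_protein("MKWVTFISLLR", p0), c("MK", "WVTFISLLR"))
  expect_setequal(digest_protein("AKPR", p0), c("AKPR"))
  p1 <- digest_params(1, min_len = 1, max_len = 100)
  expect_setequal(digest_protein("MKWVTFISLLR", p1),
                  c("MK", "WVTFISLLR", "MKWVTFISLLR"))
  # default length filter drops sub-7-mers
  expect_false("MK" %in% digest_protein("MKWVTFISLLR", digest_params(0)))
  expect_error(digest_protein(""), "non-empty")
})

test_that("reference subtraction removes I/L-ambiguous reference peptides and is idempotent", {
  ref <- c(p1 = "MKWVTFISLLRSAMPLEK")
  psms <- data.frame(
    sample_id = "S1",
    peptide = c("WVTFISLLR",   # exact reference tryptic peptide
                "WVTFLSLIR",   # differs only by I<->L swaps
                "WVTFQSLLR",   # true mismatch -> retained
                "NEWPEPTIDEK", # non-reference but fails q
                "NEWPEPTLDEK"),# non-reference but not validated
    score = 25, q_value = c(0.001, 0.001, 0.001, 0.05, 0.001),
    validated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- filter_nonreference(psms, ref)
  expect_equal(out$peptide, "WVTFQSLLR")
  expect_equal(out$key, "WVTFQSLLR")
  # idempotence
  again <- filter_nonreference(out[names(psms)], ref)
  expect_equal(again$peptide, out$peptide)
  expect_error(filter_nonreference(psms, character(0)), "empty reference")
})

make_tiny_db <- function() {
  build_cohort_db(data.frame(
    sample_id = c("S1", "S1", "S2", "S2"),
    prediction_type = c("in_frame", "frameshift", "in_frame", "in_frame"),
    original_header = c("gA|t1|v1", "gA|t1|v2", "gB|t2|v3", "gA|t1|v1"),
    seq = c("MAAACCCDDDK", "MAAACCCEEEK", "MSHAREDPEPK", "MAAACCCDDDK"),
    stringsAsFactors = FALSE))
}

test_that("database mapping enforces the unique-gene rule and derives classes", {
  db <- make_tiny_db()
  cand <- data.frame(
    sample_id = c("S1", "S1", "S2", "S1"),
    peptide = c("AAACCC",        # matches two gA records, two types -> multi
                "SHAREDPEP",     # gB only
                "QQQQQQQ",       # no hit -> discarded
                "AAACCCDDDK"),   # single gA record -> in_frame
    score = 25, q_value = 0.001, validated = TRUE,
    stringsAsFactors = FALSE)
  cand$key <- collapse_il(cand$peptide)
  got <- map_to_variant_db(cand, db)
  expect_setequal(got$key, c("AAACCC", "SHAREDPEP", "AAACCCDDDK"))
  expect_equal(got$variant_class[got$key == "AAACCC"], "multi")
  expect_equal(got$gene_id[got$key == "AAACCC"], "gA")
  expect_equal(got$variant_class[got$key == "AAACCCDDDK"], "in_frame")

  # a peptide occurring in sequences of two genes is discarded
  db2 <- build_cohort_db(data.frame(
    sample_id = c("S1", "S1"),
    prediction_type = c("in_frame", "in_frame"),
    original_header = c("gA|t1|v1", "gB|t2|v2"),
    seq = c("MWWPPQQKA", "CWWPPQQKDDD"), stringsAsFactors = FALSE))
  cand2 <- data.frame(sample_id = "S1", peptide = "WWPPQQK", score = 25,
                      q_value = 0.001, validated = TRUE,
                      stringsAsFactors = FALSE)
  cand2$key <- collapse_il(cand2$peptide)
  expect_equal(nrow(map_to_variant_db(cand2, db2)), 0)
})

test_that("missed-cleavage merging is transitive, order invariant and variant-aware", {
  base <- data.frame(
    key = c("ACDEFK", "ACDEFKGHMR", "WWWWYYYK"),
    gene_id = c("gA", "gA", "gA"),
    variant_class = "in_frame",
    member_peptides = c("ACDEFK", "ACDEFKGHMR", "WWWWYYYK"),
    md5_hits = c("m1", "m1", "m2"),   # extension shares m1; third is another variant
    samples = c("S1", "S2", "S1"),
    stringsAsFactors = FALSE)
  got <- merge_missed_cleavages(base)
  expect_equal(nrow(got), 2)
  merged <- got[got$key == "ACDEFK", ]
  expect_equal(merged$samples, "S1;S2")             # presence union
  expect_equal(merged$member_peptides, "ACDEFK;ACDEFKGHMR")
  # peptides on different variants of the same gene are not merged
  expect_true("WWWWYYYK" %in% got$key)

  # order invariance / fixpoint
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(merge_missed_cleavages(base[perm, ]), got)
  }
  expect_equal(merge_missed_cleavages(got), got)

  # substring relation without shared evidence does not merge
  base2 <- base
  base2$md5_hits <- c("m1", "m9", "m2")
  expect_equal(nrow(merge_missed_cleavages(base2)), 3)
})

test_that("presence matrix is binary with correct patient counts and column order", {
  recs <- data.frame(key = c("PEPK", "QQQR"), gene_id = c("gA", "gB"),
                     variant_class = "in_frame",
                     member_peptides = c("PEPK", "QQQR"),
                     md5_hits = c("m1", "m2"),
                     samples = c("S1", "S1;S2;S3"),
                     stringsAsFactors = FALSE)
  pm <- c(S1 = "P1", S2 = "P1", S3 = "P2")
  got <- build_presence_matrix(recs, c("S3", "S1", "S2"), pm)
  expect_equal(colnames(got$matrix), c("S3", "S1", "S2"))
  expect_equal(unname(got$matrix["PEPK", ]), c(0L, 1L, 0L))
  expect_equal(sum(got$matrix["PEPK", ]), 1)
  expect_equal(unname(got$n_patients), c(1L, 2L))   # 3 samples, 2 patients
  expect_true(all(got$matrix %in% c(0L, 1L)))
  expect_true(all(rowSums(got$matrix) >= 1))
  expect_error(build_presence_matrix(recs, c("S1", "S9"), pm), "patient_map")

  kept <- filter_min_patients(got, min_patients = 3)
  expect_equal(nrow(kept$matrix), 0)
  kept2 <- filter_min_patients(got, min_patients = 2)
  expect_equal(rownames(kept2$matrix), "QQQR")      # boundary: 2 >= 2 included
})

test_that("NRP calling on the synthetic cohort has clean reference subtraction", {
  co <- test_cohort()
  db <- test_cohort_db()
  res <- nrp_call(co$psms, co$reference$proteome, db,
                  co$samples$sample_id, patient_map_of(co))
  expect_gt(nrow(res$catalog), 0)
  hay <- paste(collapse_il(unname(co$reference$proteome)), collapse = "#")
  leaks <- vapply(res$catalog$key, function(k) grepl(k, hay, fixed = TRUE),
                  logical(1))
  expect_false(any(leaks))
  expect_true(all(res$presence$matrix %in% c(0L, 1L)))
  expect_true(all(rowSums(res$presence$matrix) >= 1))
  expect_equal(res$catalog$n_patients,
               unname(res$presence$n_patients[res$catalog$key]))
})
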