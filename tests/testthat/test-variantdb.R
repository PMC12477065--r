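test_that("frame effect follows the mod-3 allele length rule", {
  expect_equal(classify_frame_effect("A", "G"), "in_frame")
  expect_equal(classify_frame_effect("A", "ACCC"), "in_frame")
  expect_equal(classify_frame_effect("AC", "A"), "frameshift")
  expect_equal(classify_frame_effect(c("A", "ACTG"), c("T", "A")),
               c("in_frame", "in_frame"))
  expect_error(classify_frame_effect("A", "A"), "differ")
  expect_error(classify_frame_effect("A", ""), "ACGT")
})

test_that("window combination enumeration matches the power-set oracle", {
  # three variants inside one 30-aa window -> all 7 subsets
  v <- make_inframe_variants(c(5, 10, 20) * 3)
  got <- enumerate_window_combinations(v)
  expect_length(got, 7)
  expect_equal(canon_subsets(got), canon_subsets(oracle_combinations(v)))

  # far-apart pair: only singletons, never the pair
  v2 <- make_inframe_variants(c(5, 100) * 3)
  got2 <- enumerate_window_combinations(v2)
  expect_length(got2, 2)
  expect_equal(canon_subsets(got2), canon_subsets(oracle_combinations(v2)))

  # single variant -> exactly one subset
  expect_length(enumerate_window_combinations(make_inframe_variants(30)), 1)

  # overlapping variants (del spanning nt 12-15, ins anchored at nt 13)
  # are never combined
  v3 <- data.frame(pos = c(12, 13), ref_allele = c("AAAA", "A"),
                   alt_allele = c("A", "ATTT"), stringsAsFactors = FALSE)
  got3 <- enumerate_window_combinations(v3)
  expect_equal(canon_subsets(got3), canon_subsets(oracle_combinations(v3)))
  expect_length(got3, 2)

  # randomised property check against the oracle
  set.seed(11)
  for (r in 1:25) {
    n <- sample(2:8, 1)
    types <- sample(c("snv", "ins", "del"), n, replace = TRUE)
    pos <- sort(sample(0:360, n))
    v <- make_inframe_variants(pos, types)
    got <- enumerate_window_combinations(v)
    expect_equal(canon_subsets(got), canon_subsets(oracle_combinations(v)),
                 info = paste("instance", r))
  }
})

test_that("per-gene combination cap uses exact subset counts and boundary", {
  big <- variantdb_params(max_combinations_per_gene = 10L^6L)
  v14 <- make_inframe_variants(seq(0, 39, 3))   # 14 SNVs in one window
  expect_equal(enumerate_window_combinations(v14, big, count_only = TRUE),
               2^14 - 1)
  v13 <- make_inframe_variants(seq(0, 36, 3))
  expect_equal(enumerate_window_combinations(v13, big, count_only = TRUE),
               2^13 - 1)
  p <- variantdb_params()
  expect_true(gene_exceeds_cap(2^14 - 1, p))    # 16383 > 10000 -> drop
  expect_false(gene_exceeds_cap(2^13 - 1, p))   # 8191 -> keep
  expect_false(gene_exceeds_cap(10000, p))      # boundary kept
  expect_true(gene_exceeds_cap(10001, p))       # boundary dropped
  expect_equal(enumerate_window_combinations(make_inframe_variants(integer(0)),
                                             p, count_only = TRUE), 0)
  # count short-circuits instead of enumerating astronomically many subsets
  v30 <- make_inframe_variants(seq(0, 87, 3))
  expect_identical(enumerate_window_combinations(v30, p, count_only = TRUE), Inf)
})

test_that("variant application translates the affected region correctly", {
  tx <- list(gene_id = "g1", transcript_id = "t1", cds_seq = "ATGAAATGA")
  # SNV AAA->GAA: protein MK -> ME
  snv <- data.frame(pos = 3, ref_allele = "A", alt_allele = "G",
                    stringsAsFactors = FALSE)
  r <- apply_and_translate(tx, snv)
  expect_equal(r$seq, "ME")
  expect_equal(r$prediction_type, "in_frame")

  # frameshift: insert C before the second codon -> ATG CAA ATG A -> MQM
  fs <- data.frame(pos = 2, ref_allele = "G", alt_allele = "GC",
                   stringsAsFactors = FALSE)
  r2 <- apply_and_translate(tx, fs)
  expect_equal(r2$seq, "MQM")
  expect_equal(r2$prediction_type, "frameshift")

  # synonymous change -> no record; empty subset -> no record
  syn <- data.frame(pos = 5, ref_allele = "A", alt_allele = "G",
                    stringsAsFactors = FALSE)  # AAA->AAG, both Lys
  expect_null(apply_and_translate(tx, syn))
  expect_null(apply_and_translate(tx, snv[0, , drop = FALSE]))

  # stop gain truncates
  tx2 <- list(gene_id = "g1", transcript_id = "t1",
              cds_seq = "ATGAAAAAAAAATGA")     # MKKK
  sg <- data.frame(pos = 3, ref_allele = "AAA", alt_allele = "TGA",
                   stringsAsFactors = FALSE)
  r3 <- apply_and_translate(tx2, sg)
  expect_equal(r3$seq, "M")

  # ref mismatch is a hard error naming the offset
  bad <- data.frame(pos = 3, ref_allele = "C", alt_allele = "G",
                    stringsAsFactors = FALSE)
  expect_error(apply_and_translate(tx, bad), "mismatch")
})

test_that("in-frame records carry the flanking window and frameshifts run to the stop", {
  set.seed(21)
  codons <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                          paste0), c("A","C","G","T"), paste0)),
                    c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(codons, 120, replace = TRUE), collapse = ""),
                "TAA")
  tx <- list(gene_id = "g1", transcript_id = "t1", cds_seq = cds)
  ref_prot <- proteovar:::translate_to_stop(cds)
  v <- data.frame(pos = 180, ref_allele = substr(cds, 181, 181),
                  alt_allele = setdiff(c("A","C","G","T"),
                                       substr(cds, 181, 181))[1],
                  stringsAsFactors = FALSE)
  r <- apply_and_translate(tx, v)
  if (!is.null(r)) {  # non-synonymous draw
    expect_lte(nchar(r$seq), 61)       # <= 2*window + 1 residues
    expect_false(grepl(r$seq, ref_prot, fixed = TRUE))
  }
  fs <- data.frame(pos = 180, ref_allele = substr(cds, 181, 182),
                   alt_allele = substr(cds, 181, 181),
                   stringsAsFactors = FALSE)
  r2 <- apply_and_translate(tx, fs)
  expect_equal(r2$prediction_type, "frameshift")
  expect_false(grepl("*", r2$seq, fixed = TRUE))
})

test_that("cohort database dedups by MD5, is order invariant and round-trips", {
  recs <- data.frame(
    sample_id = c("S1", "S2", "S1"),
    prediction_type = c("in_frame", "in_frame", "frameshift"),
    original_header = c("gA|t1|x", "gA|t1|x", "gB|t2|y"),
    seq = c("MPEPTIDEK", "MPEPTIDEK", "MFRAMEK"),
    stringsAsFactors = FALSE)
  db <- build_cohort_db(recs)
  expect_length(db$fasta_records, 2)          # dedup: shared sequence once
  expect_equal(nrow(db$provenance), 3)        # provenance keeps every row
  expect_equal(sum(db$provenance$md5 == proteovar:::md5_hex("MPEPTIDEK")), 2)

  # MD5 headers verify against an independent digest implementation
  for (h in names(db$fasta_records)) {
    expect_equal(h, as.character(openssl::md5(db$fasta_records[[h]])))
  }

  # input order invariance
  db2 <- build_cohort_db(recs[c(3, 1, 2), ])
  expect_identical(db, db2)

  # file round trip reconstructs an equal database
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_cohort_db(db, fa, tsv)
  db3 <- read_cohort_db(fa, tsv)
  expect_equal(db$fasta_records, db3$fasta_records)
  expect_equal(db$provenance, db3$provenance)

  expect_error(build_cohort_db(transform(recs, prediction_type = "weird")),
               "prediction_type")
})

test_that("per-sample prediction rejects out-of-CDS variants and drops capped genes", {
  tx <- data.frame(gene_id = "g1", transcript_id = "t1",
                   cds_seq = "ATGAAATGCAAATGA", stringsAsFactors = FALSE)
  v <- data.frame(sample_id = "S1", transcript_id = "t1",
                  pos = c(3, 999), ref_allele = c("A", "A"),
                  alt_allele = c("G", "T"), stringsAsFactors = FALSE)
  expect_warning(out <- predict_variant_proteins(tx, v), "outside CDS")
  expect_equal(nrow(out$records), 1)
  expect_equal(out$dropped_genes, character(0))

  # tiny cap forces the gene out
  v2 <- data.frame(sample_id = "S1", transcript_id = "t1",
                   pos = c(3, 6), ref_allele = c("A", "A"),
                   alt_allele = c("G", "T"), stringsAsFactors = FALSE)
  out2 <- predict_variant_proteins(tx, v2,
                                   variantdb_params(max_combinations_per_gene = 2))
  expect_equal(out2$dropped_genes, "g1")
  expect_equal(nrow(out2$records), 0)
})
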