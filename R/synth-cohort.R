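#' Configuration for the synthetic multi-metastasis cohort generator
#'
#' Defaults emulate the structure of a post-mortem multi-metastasis
#' melanoma cohort: 24 patients with 1-9 distant metastases each, four
#' proteomic clusters with cluster-linked survival, planted SNVs and
#' in-frame/frameshift indels with known reference-population allele
#' frequencies, and label-free abundance with left-censored (MNAR)
#' missingness.
#'
#' @param n_patients Number of patients.
#' @param metastases_per_patient Integer range `c(min, max)` of metastases
#'   per patient (drawn uniformly).
#' @param n_genes Number of genes.
#' @param n_transcripts_per_gene Coding transcripts per gene.
#' @param cds_length_range CDS length range in nt; both ends must be
#'   multiples of 3.
#' @param n_snv,n_inframe_indel,n_frameshift_indel Planted variant counts.
#' @param af_spectrum Mixture weights over AF classes
#'   `c(absent, rare, common)`: absent from the reference population,
#'   in (0, 1%], or above 1%.
#' @param concordance Probability that a metastasis of a carrier patient
#'   carries the patient's variant (1 = all metastases share variants).
#' @param n_clusters Number of planted proteomic clusters (>= 2).
#' @param cluster_effect_size Log2-intensity shift of a cluster's pathway
#'   block.
#' @param noise_sd Within-cluster biological standard deviation
#'   (log2 units) — the sigma that `cluster_effect_size` is measured
#'   against.
#' @param missing_frac Overall fraction of missing abundance cells,
#'   concentrated at low intensities (MNAR).
#' @param n_replicates Proteomic replicates per sample.
#' @param survival_hazard_ratio_per_cluster Positive hazard multipliers,
#'   one per cluster.
#' @param base_hazard Baseline exponential hazard (per month).
#' @param censor_time Administrative censoring time (months).
#' @param n_ref_psms Reference-peptide PSM rows per sample.
#' @param n_noise_psms Decoy-like noise PSM rows per sample.
#' @param noise_validated_frac Fraction of noise PSMs carrying a spurious
#'   validation flag (they exercise the unexplained-peptide discard rule).
#' @param seed Integer master seed; all outputs are byte-identical under
#'   the same configuration.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_patients = 24L,
                         metastases_per_patient = c(1L, 9L),
                         n_genes = 60L,
                         n_transcripts_per_gene = 1L,
                         cds_length_range = c(300L, 900L),
                         n_snv = 120L,
                         n_inframe_indel = 30L,
                         n_frameshift_indel = 30L,
                         af_spectrum = c(absent = 0.5, rare = 0.2, common = 0.3),
                         concordance = 0.5,
                         n_clusters = 4L,
                         cluster_effect_size = 2,
                         noise_sd = 1,
                         missing_frac = 0.10,
                         n_replicates = 2L,
                         survival_hazard_ratio_per_cluster = c(3, 1, 3, 1),
                         base_hazard = 0.02,
                         censor_time = 120,
                         n_ref_psms = 40L,
                         n_noise_psms = 20L,
                         noise_validated_frac = 0.5,
                         seed = 42L) {
  if (any(cds_length_range %% 3L != 0L)) {
    stop("configuration error: cds_length_range must be multiples of 3")
  }
  fracs <- c(concordance, missing_frac, noise_validated_frac, af_spectrum)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]")
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (length(survival_hazard_ratio_per_cluster) != n_clusters ||
      any(survival_hazard_ratio_per_cluster <= 0)) {
    stop("survival_hazard_ratio_per_cluster needs one positive value per cluster")
  }
  cfg <- as.list(environment())
  cfg$af_spectrum <- af_spectrum / sum(af_spectrum)
  structure(cfg, class = "synth_config")
}

#' Generate the synthetic reference: transcripts, proteome, gene sets
#'
#' Coding sequences start with ATG, end with a single stop codon, and
#' contain no internal stops; the reference proteome holds one entry per
#' transcript. Genes are partitioned into named pathways used downstream
#' as the planted cluster blocks. Deterministic under the config seed.
#'
#' @param config [synth_config()].
#' @return List: `transcripts` (data frame `gene_id`, `transcript_id`,
#'   `strand`, `cds_seq`), `proteome` (named by transcript id),
#'   `gene_sets` (named list partitioning the genes).
#' @export
generate_reference <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  codons <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  n_tx <- config$n_genes * config$n_transcripts_per_gene
  gene_id <- rep(sprintf("g%03d", seq_len(config$n_genes)),
                 each = config$n_transcripts_per_gene)
  transcript_id <- sprintf("t%03d_%d", rep(seq_len(config$n_genes),
                                           each = config$n_transcripts_per_gene),
                           rep(seq_len(config$n_transcripts_per_gene),
                               times = config$n_genes))
  lo <- config$cds_length_range[1] %/% 3L
  hi <- config$cds_length_range[2] %/% 3L
  cds <- vapply(seq_len(n_tx), function(i) {
    n_codons <- sample(lo:hi, 1L)
    paste0("ATG",
           paste(sample(codons, n_codons - 2L, replace = TRUE), collapse = ""),
           sample(stops, 1L))
  }, character(1))
  transcripts <- data.frame(gene_id = gene_id, transcript_id = transcript_id,
                            strand = "+", cds_seq = cds,
                            stringsAsFactors = FALSE)
  proteome <- setNames(vapply(cds, translate_to_stop, character(1),
                              USE.NAMES = FALSE), transcript_id)
  n_pathways <- max(config$n_clusters + 2L,
                    ceiling(config$n_genes / 12))
  pathway_of <- rep_len(seq_len(n_pathways), config$n_genes)
  genes <- unique(gene_id)
  gene_sets <- split(genes, sprintf("pathway_%02d", pathway_of))
  list(transcripts = transcripts, proteome = proteome, gene_sets = gene_sets)
}

# Sample sheet: patients, metastasis samples, locations, tumour content.
make_samples <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  n_meta <- sample(config$metastases_per_patient[1]:config$metastases_per_patient[2],
                   config$n_patients, replace = TRUE)
  patient_id <- rep(sprintf("MF%02d", seq_len(config$n_patients)), n_meta)
  sample_id <- paste0(patient_id,
                      unlist(lapply(n_meta, function(k) LETTERS[seq_len(k)])))
  locations <- c("skin", "lymph_node", "liver", "lung", "brain", "intestine")
  data.frame(sample_id = sample_id, patient_id = patient_id,
             location = sample(locations, length(sample_id), replace = TRUE),
             tumour_content = round(runif(length(sample_id), 40, 100), 1),
             stringsAsFactors = FALSE)
}

#' Plant variants on the synthetic transcripts
#'
#' Draws SNVs, in-frame indels (+-3 nt) and frameshift indels (+-1/2 nt)
#' at uniform CDS positions (sparing the start and stop codons), assigns
#' each a true reference-population AF class from the configured
#' spectrum, and distributes carriers: each variant is carried by one or
#' a few patients, and each metastasis of a carrier patient carries it
#' with probability `concordance` (at least one always does).
#'
#' @param reference Output of [generate_reference()].
#' @param samples Sample sheet (internal; supplied by
#'   [simulate_cohort()]).
#' @param config [synth_config()].
#' @return List: `variants` (data frame with true AF and class),
#'   `carriers` (long data frame `variant_id`, `sample_id`).
#' @export
plant_variants <- function(reference, samples, config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  tx <- reference$transcripts
  n_total <- config$n_snv + config$n_inframe_indel + config$n_frameshift_indel
  kind <- rep(c("snv", "inframe", "frameshift"),
              c(config$n_snv, config$n_inframe_indel, config$n_frameshift_indel))
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    ti <- sample.int(nrow(tx), 1L)
    L <- nchar(tx$cds_seq[ti])
    if (kind[i] == "snv") {
      pos <- sample(3:(L - 4L), 1L)
      ref <- substr(tx$cds_seq[ti], pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    } else {
      d <- if (kind[i] == "inframe") 3L else sample(1:2, 1L)
      if (runif(1) < 0.5) {      # insertion after the anchor base
        pos <- sample(3:(L - 4L), 1L)
        ref <- substr(tx$cds_seq[ti], pos + 1L, pos + 1L)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), d,
                                        replace = TRUE), collapse = ""))
      } else {                    # deletion anchored at the kept base
        pos <- sample(3:(L - 4L - d), 1L)
        ref <- substr(tx$cds_seq[ti], pos + 1L, pos + 1L + d)
        alt <- substr(ref, 1L, 1L)
      }
    }
    rows[[i]] <- data.frame(transcript_id = tx$transcript_id[ti],
                            gene_id = tx$gene_id[ti], pos = pos,
                            ref_allele = ref, alt_allele = alt,
                            stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, rows)
  v <- v[!duplicated(v[c("transcript_id", "pos", "ref_allele", "alt_allele")]), ,
         drop = FALSE]
  v$variant_id <- sprintf("v%04d", seq_len(nrow(v)))
  v$frame_effect <- classify_frame_effect(v$ref_allele, v$alt_allele)
  v$variant_key <- with(v, paste(transcript_id, pos, ref_allele, alt_allele,
                                 sep = ":"))
  cls <- sample(c("absent", "rare", "common"), nrow(v), replace = TRUE,
                prob = config$af_spectrum)
  v$af <- ifelse(cls == "absent", NA_real_,
                 ifelse(cls == "rare", runif(nrow(v), 1e-4, 0.01),
                        runif(nrow(v), 0.011, 0.5)))
  v$af_class <- classify_af(v$af)

  patients <- unique(samples$patient_id)
  carrier_rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    k <- sample(1:4, 1L, prob = c(0.55, 0.25, 0.12, 0.08))
    pats <- sample(patients, min(k, length(patients)))
    sids <- character(0)
    for (p in pats) {
      metas <- samples$sample_id[samples$patient_id == p]
      carry <- metas[runif(length(metas)) < config$concordance]
      if (length(carry) == 0L) carry <- sample(metas, 1L)
      sids <- c(sids, carry)
    }
    carrier_rows[[i]] <- data.frame(variant_id = v$variant_id[i],
                                    sample_id = sids, stringsAsFactors = FALSE)
  }
  carriers <- do.call(rbind, carrier_rows)
  list(variants = v, carriers = carriers)
}

# Ground-truth NRP peptides per variant: tryptic peptides of the
# single-variant protein whose I/L-collapsed form does not occur in the
# collapsed reference proteome.
planted_nrp_peptides <- function(reference, planted,
                                 dparams = digest_params()) {
  tx <- reference$transcripts
  hay <- collapsed_haystack(reference$proteome)
  v <- planted$variants
  out <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    t_row <- tx[tx$transcript_id == v$transcript_id[i], , drop = FALSE]
    mut <- apply_variants_nt(t_row$cds_seq, v[i, , drop = FALSE])
    prot <- translate_to_stop(mut$seq)
    if (!nzchar(prot)) next
    peps <- digest_protein(prot, dparams)
    if (length(peps) == 0L) next
    novel <- peps[!vapply(collapse_il(peps),
                          function(p) grepl(p, hay, fixed = TRUE), logical(1))]
    if (length(novel) == 0L) next
    out[[i]] <- data.frame(variant_id = v$variant_id[i],
                           gene_id = v$gene_id[i], peptide = novel,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(variant_id = character(0), gene_id = character(0),
                      peptide = character(0), stringsAsFactors = FALSE)
  }
  res
}

#' Simulate the cohort's observable data
#'
#' Produces per-sample PSM tables (reference tryptic peptides, planted
#' variant peptides and decoy-like noise, with hyperscore-like scores and
#' rank-based q-values), a raw abundance matrix with planted cluster
#' blocks, replicates and MNAR missingness, the clinical table with
#' cluster-linked exponential survival, and the reference-population AF
#' table.
#'
#' @param reference,planted Outputs of [generate_reference()] and
#'   [plant_variants()].
#' @param samples Sample sheet.
#' @param config [synth_config()].
#' @param with_proteogenomics When `FALSE`, skip the PSM tables and planted
#'   peptide lists (the expensive proteogenomic observables); the abundance,
#'   clinical and survival outputs are unchanged because each section draws
#'   from its own seed stream.
#' @return List: `psms`, `abundance_raw`, `replicate_map`, `clinical`,
#'   `survival`, `af_table`, `true_clusters`, `planted_peptides`,
#'   `planted_peptides_by_sample`.
#' @export
simulate_observations <- function(reference, planted, samples, config,
                                  with_proteogenomics = TRUE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  n_s <- nrow(samples)

  ## ---- PSM tables (own seed stream) -------------------------------------
  psms <- NULL; planted_peps <- NULL; pbs <- NULL
  if (with_proteogenomics) {
    planted_peps <- planted_nrp_peptides(reference, planted)
    set.seed(config$seed + 3L)
    ref_pep_pool <- unique(unlist(lapply(reference$proteome, digest_protein)))
    pep_by_variant <- split(planted_peps$peptide, planted_peps$variant_id)
    psm_rows <- vector("list", n_s)
    for (si in seq_len(n_s)) {
      s <- samples$sample_id[si]
      vids <- planted$carriers$variant_id[planted$carriers$sample_id == s]
      true_peps <- unique(unlist(pep_by_variant[intersect(vids, names(pep_by_variant))]))
      ref_peps <- sample(ref_pep_pool, min(config$n_ref_psms, length(ref_pep_pool)))
      noise_peps <- vapply(seq_len(config$n_noise_psms), function(j) {
        paste(sample(AA_ALPHABET20, sample(8:15, 1L), replace = TRUE),
              collapse = "")
      }, character(1))
      pep <- c(true_peps, ref_peps, noise_peps)
      n_true <- length(true_peps) + length(ref_peps)
      score <- c(rnorm(n_true, 25, 5), rnorm(length(noise_peps), 10, 3))
      validated <- c(rep(TRUE, n_true),
                     runif(length(noise_peps)) < config$noise_validated_frac)
      q <- 0.01 * rank(-score, ties.method = "average") / length(score)
      psm_rows[[si]] <- data.frame(sample_id = s, peptide = pep, score = score,
                                   q_value = q, validated = validated,
                                   stringsAsFactors = FALSE)
    }
    psms <- do.call(rbind, psm_rows)
    rownames(psms) <- NULL
  }

  ## ---- abundance matrix with planted cluster blocks (own seed stream) ---
  set.seed(config$seed + 4L)
  true_clusters <- setNames(
    sample(rep_len(seq_len(config$n_clusters), n_s)), samples$sample_id)
  genes <- unique(reference$transcripts$gene_id)
  base <- rnorm(length(genes), 17, 2)
  block_sets <- reference$gene_sets[seq_len(config$n_clusters)]
  rep_ids <- as.vector(t(outer(samples$sample_id,
                               paste0("_R", seq_len(config$n_replicates)),
                               paste0)))
  replicate_map <- setNames(rep(samples$sample_id,
                                each = config$n_replicates), rep_ids)
  log2_mat <- matrix(NA_real_, length(genes), length(rep_ids),
                     dimnames = list(genes, rep_ids))
  rep_shift <- rnorm(length(rep_ids), 0, 0.3)
  for (si in seq_len(n_s)) {
    s <- samples$sample_id[si]
    eff <- numeric(length(genes))
    blk <- block_sets[[true_clusters[s]]]
    eff[genes %in% blk] <- config$cluster_effect_size
    sample_level <- base + eff + rnorm(length(genes), 0, config$noise_sd)
    cols <- which(replicate_map == s)
    for (ci in cols) {
      log2_mat[, ci] <- sample_level + rep_shift[ci] +
        rnorm(length(genes), 0, 0.15)
    }
  }
  raw <- 2^log2_mat
  if (config$missing_frac > 0) {
    vals <- as.vector(log2_mat)
    steep <- 1.5
    f <- function(t) mean(stats::plogis((t - vals) / steep)) - config$missing_frac
    t0 <- stats::uniroot(f, range(vals) + c(-20, 20))$root
    p_miss <- stats::plogis((t0 - log2_mat) / steep)
    raw[runif(length(raw)) < p_miss] <- NA
  }

  ## ---- clinical + survival (own seed stream) ----------------------------
  set.seed(config$seed + 5L)
  hr <- config$survival_hazard_ratio_per_cluster
  pat <- unique(samples$patient_id)
  surv_rows <- lapply(pat, function(p) {
    cl <- true_clusters[samples$sample_id[samples$patient_id == p]]
    frac <- tabulate(cl, nbins = config$n_clusters) / length(cl)
    h <- config$base_hazard * sum(frac * hr)
    t_raw <- rexp(1, rate = h)
    data.frame(patient_id = p, time = min(t_raw, config$censor_time),
               event = as.integer(t_raw <= config$censor_time),
               stringsAsFactors = FALSE)
  })
  survival_tab <- do.call(rbind, surv_rows)

  af_table <- planted$variants[!is.na(planted$variants$af),
                               c("variant_key", "af")]
  rownames(af_table) <- NULL

  if (with_proteogenomics) {
    pbs <- merge(planted$carriers, planted_peps, by = "variant_id")
    pbs <- pbs[order(pbs$sample_id, pbs$variant_id, pbs$peptide), , drop = FALSE]
    rownames(pbs) <- NULL
  }

  list(psms = psms, abundance_raw = raw, replicate_map = replicate_map,
       clinical = samples, survival = survival_tab, af_table = af_table,
       true_clusters = true_clusters, planted_peptides = planted_peps,
       planted_peptides_by_sample = pbs)
}

#' Simulate a complete synthetic cohort
#'
#' Chains [generate_reference()], the sample sheet, [plant_variants()] and
#' [simulate_observations()]; all randomness derives from `config$seed`,
#' so identical configurations give identical cohorts.
#'
#' @param config [synth_config()].
#' @param with_proteogenomics Passed to [simulate_observations()].
#' @return List of class `synth_cohort` bundling reference, samples,
#'   planted ground truth and observations.
#' @export
simulate_cohort <- function(config = synth_config(), with_proteogenomics = TRUE) {
  reference <- generate_reference(config)
  samples <- make_samples(config)
  planted <- plant_variants(reference, samples, config)
  obs <- simulate_observations(reference, planted, samples, config,
                               with_proteogenomics = with_proteogenomics)
  structure(c(list(config = config, reference = reference, samples = samples,
                   planted = planted), obs),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d metastases, %d genes, %d planted variants\n",
              length(unique(x$samples$patient_id)), nrow(x$samples),
              length(unique(x$reference$transcripts$gene_id)),
              nrow(x$planted$variants)))
  invisible(x)
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Writes transcripts and proteome FASTA, per-sample VCF 4.2, per-sample
#' PSM TSVs, the raw abundance TSV, clinical and AF tables, gene sets as
#' GMT, and the ground truth as JSON.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- cohort$reference$transcripts
  write_fasta(setNames(tx$cds_seq, tx$transcript_id),
              file.path(dir, "transcripts.fasta"), type = "DNA")
  write_fasta(cohort$reference$proteome, file.path(dir, "proteome.fasta"),
              type = "AA")
  write_gmt(cohort$reference$gene_sets, file.path(dir, "genesets.gmt"))
  v <- merge(cohort$planted$carriers, cohort$planted$variants,
             by = "variant_id")
  for (s in unique(cohort$samples$sample_id)) {
    vs <- v[v$sample_id == s, , drop = FALSE]
    vs <- vs[order(vs$transcript_id, vs$pos), , drop = FALSE]
    write_vcf(vs, file.path(dir, sprintf("variants.%s.vcf", s)), sample_id = s)
  }
  for (s in unique(cohort$psms$sample_id)) {
    write.table(cohort$psms[cohort$psms$sample_id == s, , drop = FALSE],
                file.path(dir, sprintf("psm.%s.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_matrix_tsv(cohort$abundance_raw, file.path(dir, "abundance.tsv"),
                   feature_col = "protein_id")
  clin <- merge(cohort$clinical, cohort$survival, by = "patient_id")
  write.table(clin[order(clin$sample_id), ], file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$af_table, file.path(dir, "af_reference.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- list(variants = cohort$planted$variants,
               carriers = cohort$planted$carriers,
               planted_peptides = cohort$planted_peptides,
               true_clusters = as.list(cohort$true_clusters),
               survival_hazard_ratio_per_cluster =
                 cohort$config$survival_hazard_ratio_per_cluster)
    jsonlite::write_json(gt, file.path(dir, "groundtruth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
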