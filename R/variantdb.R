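#' Parameters for variant protein database construction
#'
#' @param window_aa Width, in residues, of the window within which in-frame
#'   variants are combined. Windows are anchored at each variant's first
#'   affected residue.
#' @param max_combinations_per_gene A gene is dropped for a sample when the
#'   number of generated variant combinations across all its transcripts
#'   exceeds this cap; guards against combinatorial explosion of the search
#'   space in hypermutated genes.
#' @return List of class `variantdb_params`.
#' @export
variantdb_params <- function(window_aa = 30L, max_combinations_per_gene = 10000L) {
  stopifnot(window_aa >= 1L, max_combinations_per_gene >= 1L)
  structure(list(window_aa = as.integer(window_aa),
                 max_combinations_per_gene = as.integer(max_combinations_per_gene)),
            class = "variantdb_params")
}

#' Classify the frame effect of a small variant
#'
#' A variant preserves the reading frame iff the allele length difference is
#' a multiple of 3; SNVs are therefore always in-frame.
#'
#' @param ref_allele,alt_allele Character vectors of reference/alternate
#'   alleles.
#' @return Character vector: `"in_frame"` or `"frameshift"`.
#' @examples
#' classify_frame_effect("A", "G")     # SNV: in_frame
#' classify_frame_effect("AC", "A")    # 1-nt deletion: frameshift
#' @export
classify_frame_effect <- function(ref_allele, alt_allele) {
  if (any(ref_allele == alt_allele)) stop("ref and alt alleles must differ")
  if (any(!grepl("^[ACGT]+$", c(ref_allele, alt_allele)))) {
    stop("alleles must be non-empty ACGT strings")
  }
  d <- abs(nchar(alt_allele) - nchar(ref_allele))
  ifelse(d %% 3L == 0L, "in_frame", "frameshift")
}

# First and last affected residue (0-based) of a variant on the transcript
# protein. Deletions/MNVs can span several residues.
variant_aa_span <- function(pos, ref_allele) {
  cbind(start = pos %/% 3L, end = (pos + nchar(ref_allele) - 1L) %/% 3L)
}

# TRUE where variant i and j overlap on the reference (share reference bases).
variants_overlap <- function(pos_i, ref_i, pos_j, ref_j) {
  pos_i < pos_j + nchar(ref_j) & pos_j < pos_i + nchar(ref_i)
}

#' Enumerate in-frame variant combinations per amino-acid window
#'
#' For each variant, a window of `window_aa` residues anchored at the
#' variant's first affected residue is considered, and every non-empty
#' subset of the in-frame variants whose affected residues fall entirely
#' inside the window is generated. Subsets containing variants that overlap
#' on the reference are never generated (overlapping variants are mutually
#' exclusive). Subsets valid in several windows are emitted once, in a
#' deterministic order.
#'
#' @param variants Data frame of in-frame variants on one transcript for one
#'   sample, with columns `pos` (0-based CDS offset), `ref_allele`,
#'   `alt_allele`.
#' @param params [variantdb_params()].
#' @param count_only If `TRUE`, return only the number of combinations,
#'   short-circuiting (with value `Inf`) once the per-gene cap is exceeded.
#' @return List of integer vectors of row indices into `variants`, or a
#'   count when `count_only = TRUE`.
#' @export
enumerate_window_combinations <- function(variants, params = variantdb_params(),
                                          count_only = FALSE) {
  n <- nrow(variants)
  if (n == 0L) return(if (count_only) 0 else list())
  ord <- order(variants$pos, variants$ref_allele, variants$alt_allele)
  v <- variants[ord, , drop = FALSE]
  span <- variant_aa_span(v$pos, v$ref_allele)
  cap <- params$max_combinations_per_gene

  # short-circuit: a window holding m mutually compatible variants alone
  # yields 2^m - 1 distinct subsets
  if (count_only) {
    for (i in seq_len(n)) {
      win_lo <- span[i, "start"]
      win_hi <- win_lo + params$window_aa - 1L
      m <- sum(span[, "start"] >= win_lo & span[, "end"] <= win_hi)
      if (m >= 31L || 2^m - 1 > 4 * (cap + 1)) return(Inf)
    }
  }

  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 0L)
  n_out <- 0L
  for (i in seq_len(n)) {
    win_lo <- span[i, "start"]
    win_hi <- win_lo + params$window_aa - 1L
    members <- which(span[, "start"] >= win_lo & span[, "end"] <= win_hi)
    if (length(members) == 0L) next
    if (length(members) > 25L) stop("window holds too many variants to enumerate")
    for (k in seq_along(members)) {
      combs <- utils::combn(seq_along(members), k, simplify = FALSE)
      for (idx in combs) {
        s <- members[idx]
        if (length(s) > 1L) {
          ok <- TRUE
          for (a in seq_len(length(s) - 1L)) {
            if (variants_overlap(v$pos[s[a]], v$ref_allele[s[a]],
                                 v$pos[s[a + 1L]], v$ref_allele[s[a + 1L]])) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
        }
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        n_out <- n_out + 1L
        out[[n_out]] <- ord[s]
        if (count_only && n_out > cap) return(Inf)
      }
    }
  }
  if (count_only) return(n_out)
  out[seq_len(n_out)]
}

#' Decide whether a gene's variant combinations exceed the per-sample cap
#'
#' The cap is evaluated per (gene, sample) over all the gene's transcripts:
#' in-frame combination subsets plus singly-emitted frameshift variants.
#'
#' @param n_combinations Total generated combination count for the gene in
#'   one sample (may be `Inf` from the short-circuited counter).
#' @param params [variantdb_params()].
#' @return `TRUE` if the gene must be dropped for this sample.
#' @export
gene_exceeds_cap <- function(n_combinations, params = variantdb_params()) {
  n_combinations > params$max_combinations_per_gene
}

# Apply a set of non-overlapping variants to a CDS. Returns the mutated
# sequence and the 0-based nt offset of each variant's first affected base
# in the mutated sequence.
apply_variants_nt <- function(cds_seq, variants) {
  ord <- order(variants$pos)
  v <- variants[ord, , drop = FALSE]
  if (nrow(v) > 1L) {
    for (a in seq_len(nrow(v) - 1L)) {
      if (v$pos[a] + nchar(v$ref_allele[a]) > v$pos[a + 1L]) {
        stop("overlapping variants cannot be applied together")
      }
    }
  }
  out <- cds_seq
  offset <- 0L
  mut_pos <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i] + offset   # 0-based position in current mutated sequence
    ref <- v$ref_allele[i]
    have <- substr(out, p + 1L, p + nchar(ref))
    if (have != ref) {
      stop(sprintf("variant ref mismatch on %s at offset %d: expected %s, found %s",
                   v$transcript_id[i] %||% "<transcript>", v$pos[i], ref, have))
    }
    out <- paste0(substr(out, 1L, p), v$alt_allele[i],
                  substr(out, p + nchar(ref) + 1L, nchar(out)))
    mut_pos[i] <- p
    offset <- offset + nchar(v$alt_allele[i]) - nchar(ref)
  }
  list(seq = out, mut_pos = mut_pos, order = ord)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a variant subset to a transcript and translate the affected region
#'
#' In-frame subsets yield the translated region covering all affected
#' residues plus `window_aa` flanking residues on each side (clipped at the
#' protein ends), so that any tryptic peptide overlapping a variant is
#' contained in the emitted record. A frameshift variant (applied singly)
#' yields the translation from its first affected codon to the first
#' downstream stop (or transcript end), plus the upstream flank. Subsets
#' whose translation equals the reference protein (synonymous changes)
#' produce no record.
#'
#' @param transcript List or one-row data frame with `transcript_id`,
#'   `gene_id`, `cds_seq`.
#' @param variants Data frame rows of the subset (columns `pos`,
#'   `ref_allele`, `alt_allele`); a frameshift variant must be alone.
#' @param params [variantdb_params()].
#' @return `NULL` for silent subsets, else a list with `seq`,
#'   `prediction_type` (`"in_frame"` or `"frameshift"`) and `header`.
#' @export
apply_and_translate <- function(transcript, variants, params = variantdb_params()) {
  if (nrow(variants) == 0L) return(NULL)  # reference is never emitted
  fe <- classify_frame_effect(variants$ref_allele, variants$alt_allele)
  if (any(fe == "frameshift") && nrow(variants) > 1L) {
    stop("frameshift variants must be applied singly")
  }
  ref_protein <- translate_to_stop(transcript$cds_seq)
  mut <- apply_variants_nt(transcript$cds_seq, variants)
  mut_protein <- translate_to_stop(mut$seq)
  if (identical(mut_protein, ref_protein)) return(NULL)

  w <- params$window_aa
  if (all(fe == "in_frame")) {
    aa_first <- min(mut$mut_pos) %/% 3L              # 0-based, mutated frame
    v_sorted <- variants[mut$order, , drop = FALSE]
    last_nt <- max(mut$mut_pos + nchar(v_sorted$alt_allele) - 1L)
    aa_last <- last_nt %/% 3L
    lo <- max(0L, aa_first - w)
    hi <- min(nchar(mut_protein) - 1L, aa_last + w)
    if (lo > nchar(mut_protein) - 1L) {
      # all affected residues fall at/after an upstream stop gain; emit the
      # truncated tail context instead
      lo <- max(0L, nchar(mut_protein) - w)
      hi <- nchar(mut_protein) - 1L
    }
    if (hi < lo) return(NULL)
    seq <- substr(mut_protein, lo + 1L, hi + 1L)
    type <- "in_frame"
  } else {
    aa_first <- mut$mut_pos[1L] %/% 3L
    lo <- max(0L, aa_first - w)
    seq <- substr(mut_protein, lo + 1L, nchar(mut_protein))
    type <- "frameshift"
  }
  if (nchar(seq) == 0L) return(NULL)
  key <- paste(sprintf("%d%s>%s", variants$pos, variants$ref_allele,
                       variants$alt_allele), collapse = ";")
  list(seq = seq, prediction_type = type,
       header = paste(transcript$gene_id, transcript$transcript_id, type,
                      key, sep = "|"))
}

#' Predict variant protein records for one sample
#'
#' Runs the full per-sample chain: frame-effect classification, per-window
#' combination enumeration of in-frame variants, the per-gene combination
#' cap, and application/translation. Frameshift variants are emitted singly
#' and counted towards the cap.
#'
#' @param transcripts Data frame with columns `gene_id`, `transcript_id`,
#'   `cds_seq`.
#' @param variants Data frame of the sample's variants (`transcript_id`,
#'   `pos`, `ref_allele`, `alt_allele`), plus `sample_id`.
#' @param params [variantdb_params()].
#' @return List with `records` (data frame: `sample_id`, `prediction_type`,
#'   `original_header`, `seq`) and `dropped_genes` (character).
#' @export
predict_variant_proteins <- function(transcripts, variants,
                                     params = variantdb_params()) {
  sample_id <- unique(variants$sample_id)
  if (length(sample_id) > 1L) stop("one sample at a time")
  if (length(sample_id) == 0L) sample_id <- NA_character_
  tx_index <- match(variants$transcript_id, transcripts$transcript_id)
  if (anyNA(tx_index)) stop("variant on unknown transcript")
  variants$gene_id <- transcripts$gene_id[tx_index]
  variants$frame_effect <- classify_frame_effect(variants$ref_allele,
                                                 variants$alt_allele)

  # validate positions and ref alleles up front; out-of-CDS → warn + drop
  cds_len <- nchar(transcripts$cds_seq)[tx_index]
  bad <- variants$pos < 0L | variants$pos + nchar(variants$ref_allele) > cds_len
  if (any(bad)) {
    warning(sprintf("%d variant(s) outside CDS rejected", sum(bad)))
    variants <- variants[!bad, , drop = FALSE]
    tx_index <- tx_index[!bad]
  }

  recs <- list(); dropped <- character(0)
  for (g in unique(variants$gene_id)) {
    gv <- variants[variants$gene_id == g, , drop = FALSE]
    # cap decision across the gene's transcripts
    total <- 0
    per_tx <- split(gv, gv$transcript_id)
    for (tv in per_tx) {
      inf <- tv[tv$frame_effect == "in_frame", , drop = FALSE]
      total <- total + enumerate_window_combinations(inf, params, count_only = TRUE)
      total <- total + sum(tv$frame_effect == "frameshift")
      if (gene_exceeds_cap(total, params)) break
    }
    if (gene_exceeds_cap(total, params)) {
      dropped <- c(dropped, g)
      next
    }
    for (tid in names(per_tx)) {
      tv <- per_tx[[tid]]
      tx <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
      inf <- tv[tv$frame_effect == "in_frame", , drop = FALSE]
      subsets <- enumerate_window_combinations(inf, params)
      for (s in subsets) {
        r <- apply_and_translate(tx, inf[s, , drop = FALSE], params)
        if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      }
      fs <- tv[tv$frame_effect == "frameshift", , drop = FALSE]
      for (i in seq_len(nrow(fs))) {
        r <- apply_and_translate(tx, fs[i, , drop = FALSE], params)
        if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      }
    }
  }
  records <- if (length(recs)) {
    data.frame(sample_id = sample_id,
               prediction_type = vapply(recs, `[[`, "", "prediction_type"),
               original_header = vapply(recs, `[[`, "", "header"),
               seq = vapply(recs, `[[`, "", "seq"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(0), prediction_type = character(0),
               original_header = character(0), seq = character(0),
               stringsAsFactors = FALSE)
  }
  list(records = records, dropped_genes = dropped)
}

#' Build the cohort-wide deduplicated variant protein database
#'
#' Sequences predicted in any sample are deduplicated at the sequence level
#' by replacing FASTA headers with the MD5 checksum of the sequence; each
#' unique sequence is written once, while one provenance row per (sample,
#' record) retains the sample name, prediction type, original header and
#' MD5, so peptide hits can be mapped back to their transcriptomic evidence.
#' Output is invariant to the order in which sample records are supplied.
#'
#' @param records Data frame with columns `sample_id`, `prediction_type`
#'   (one of `in_frame`, `frameshift`, `splice`, `novel_orf`),
#'   `original_header`, `seq`.
#' @return List of class `cohort_variant_db`: `fasta_records` (named
#'   character, names are MD5 hex digests, sorted) and `provenance`
#'   (data frame `sample_id`, `prediction_type`, `original_header`, `md5`).
#' @export
build_cohort_db <- function(records) {
  stopifnot(all(c("sample_id", "prediction_type", "original_header", "seq")
                %in% names(records)))
  ok_types <- c("in_frame", "frameshift", "splice", "novel_orf")
  if (!all(records$prediction_type %in% ok_types)) {
    stop("unknown prediction_type")
  }
  md5 <- md5_hex(records$seq)
  # collision check: one md5 must map to exactly one sequence
  tab <- tapply(records$seq, md5, function(s) length(unique(s)))
  if (any(tab > 1L)) stop("MD5 collision between differing sequences")
  fasta <- tapply(records$seq, md5, `[`, 1L)
  fasta <- setNames(as.character(fasta), names(fasta))
  fasta <- fasta[order(names(fasta))]
  prov <- data.frame(sample_id = records$sample_id,
                     prediction_type = records$prediction_type,
                     original_header = records$original_header,
                     md5 = md5, stringsAsFactors = FALSE)
  prov <- prov[order(prov$sample_id, prov$md5, prov$prediction_type,
                     prov$original_header), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(fasta_records = fasta, provenance = prov),
            class = "cohort_variant_db")
}

#' @export
print.cohort_variant_db <- function(x, ...) {
  cat(sprintf("cohort variant db: %d unique sequences, %d provenance rows, %d samples\n",
              length(x$fasta_records), nrow(x$provenance),
              length(unique(x$provenance$sample_id))))
  invisible(x)
}

#' Write / read a cohort variant database
#'
#' The FASTA file uses the MD5 hex digest as header; the provenance TSV has
#' columns `sample_id`, `prediction_type`, `original_header`, `md5`.
#' Reading the pair back reconstructs an equal database.
#'
#' @param db A `cohort_variant_db`.
#' @param fasta_path,provenance_path Output/input files.
#' @export
write_cohort_db <- function(db, fasta_path, provenance_path) {
  write_fasta(db$fasta_records, fasta_path, type = "AA")
  write.table(db$provenance, provenance_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(db)
}

#' @rdname write_cohort_db
#' @export
read_cohort_db <- function(fasta_path, provenance_path) {
  fasta <- read_fasta(fasta_path, type = "AA")
  prov <- read.delim(provenance_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  check <- md5_hex(fasta)
  if (!identical(unname(check), names(fasta))) {
    stop("FASTA headers are not the MD5 digests of their sequences")
  }
  if (!all(prov$md5 %in% names(fasta))) {
    stop("provenance rows reference unknown MD5 digests")
  }
  fasta <- fasta[order(names(fasta))]
  prov <- prov[order(prov$sample_id, prov$md5, prov$prediction_type,
                     prov$original_header), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(fasta_records = fasta, provenance = prov),
            class = "cohort_variant_db")
}
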