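#' Tryptic digestion parameters
#'
#' @param max_missed_cleavages Maximum number of internal uncut K/R sites.
#' @param min_len,max_len Retained peptide length range in residues.
#' @return List of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 2L, min_len = 7L, max_len = 50L) {
  stopifnot(min_len <= max_len, max_missed_cleavages >= 0L)
  structure(list(enzyme = "trypsin",
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_params")
}

#' In-silico tryptic digestion of a protein
#'
#' Cleaves C-terminal of K or R except when the next residue is P, and
#' retains peptides with up to `max_missed_cleavages` internal uncut sites
#' and lengths in `[min_len, max_len]`.
#'
#' @param protein Amino-acid string.
#' @param params [digest_params()].
#' @return Character vector of unique peptides.
#' @examples
#' digest_protein("MKWVTFISLLR", digest_params(0, min_len = 1))
#' @export
digest_protein <- function(protein, params = digest_params()) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  # cleavage after position i: K/R not followed by P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  k <- length(starts)
  peps <- character(0)
  for (i in seq_len(k)) {
    for (m in 0:params$max_missed_cleavages) {
      j <- i + m
      if (j > k) break
      len <- ends[j] - starts[i] + 1L
      if (len < params$min_len || len > params$max_len) next
      peps <- c(peps, substr(protein, starts[i], ends[j]))
    }
  }
  unique(peps)
}

# Concatenate collapsed sequences with a separator so substring search can
# be done with a single fixed-pattern scan per peptide.
collapsed_haystack <- function(seqs) {
  paste(collapse_il(unname(seqs)), collapse = "#")
}

#' Filter PSMs down to candidate non-reference peptides
#'
#' A PSM survives iff its I/L-collapsed peptide is not a substring of any
#' I/L-collapsed reference protein, its q-value passes the FDR threshold,
#' and it carries the external validation flag. Peptides mappable to the
#' reference are removed even when they also match a variant sequence
#' (reference takes precedence). The operation is idempotent.
#'
#' @param psms Data frame with columns `sample_id`, `peptide`, `score`,
#'   `q_value`, `validated`.
#' @param reference Named character vector of reference proteins.
#' @param q_max FDR threshold on the PSM q-value (default 0.01).
#' @return The surviving rows of `psms`, with a `key` column holding the
#'   collapsed peptide.
#' @export
filter_nonreference <- function(psms, reference, q_max = 0.01) {
  if (length(reference) == 0L) stop("empty reference proteome")
  stopifnot(all(c("sample_id", "peptide", "q_value", "validated") %in% names(psms)))
  if (any(psms$q_value < 0 | psms$q_value > 1)) stop("q_value outside [0,1]")
  keep <- psms$q_value <= q_max & psms$validated
  psms <- psms[keep, , drop = FALSE]
  if (nrow(psms) == 0L) {
    psms$key <- character(0)
    return(psms)
  }
  hay <- collapsed_haystack(reference)
  key <- collapse_il(psms$peptide)
  uniq <- unique(key)
  in_ref <- vapply(uniq, function(p) grepl(p, hay, fixed = TRUE), logical(1))
  psms <- psms[!in_ref[match(key, uniq)], , drop = FALSE]
  psms$key <- collapse_il(psms$peptide)
  rownames(psms) <- NULL
  psms
}

#' Map candidate NRPs to the cohort variant database
#'
#' Each collapsed candidate peptide is searched against the I/L-collapsed
#' sequences of the whole cohort database (a peptide predicted in any
#' sample is searched cohort-wide). Peptides matching the sequences of more
#' than one gene, and peptides with no database hit, are discarded. The
#' variant class is derived from the prediction types of the matching
#' records; `"multi"` when one gene's matches span several types. Gene ids
#' are taken from the first `|`-separated field of the original FASTA
#' header recorded in the provenance table.
#'
#' @param candidates Output of [filter_nonreference()].
#' @param db A `cohort_variant_db`.
#' @return Data frame, one row per retained collapsed peptide: `key`,
#'   `gene_id`, `variant_class`, `member_peptides`, `md5_hits`
#'   (`;`-separated), plus a list-column-free `samples` field
#'   (`;`-separated sample ids with a surviving PSM).
#' @export
map_to_variant_db <- function(candidates, db) {
  stopifnot(inherits(db, "cohort_variant_db"))
  if (nrow(candidates) == 0L) {
    return(data.frame(key = character(0), gene_id = character(0),
                      variant_class = character(0),
                      member_peptides = character(0), md5_hits = character(0),
                      samples = character(0), stringsAsFactors = FALSE))
  }
  seqs <- db$fasta_records
  cseqs <- collapse_il(unname(seqs))
  md5s <- names(seqs)
  prov <- db$provenance
  gene_of_header <- sub("\\|.*$", "", prov$original_header)
  # md5 -> genes / types it can stem from
  md5_gene <- tapply(gene_of_header, prov$md5, function(g) unique(g))
  md5_type <- tapply(prov$prediction_type, prov$md5, function(t) unique(t))

  keys <- unique(candidates$key)
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    p <- keys[i]
    hit <- md5s[grepl(p, cseqs, fixed = TRUE)]
    if (length(hit) == 0L) next                       # unexplained peptide
    genes <- unique(unlist(md5_gene[hit]))
    if (length(genes) > 1L) next                      # multi-gene: discard
    types <- unique(unlist(md5_type[hit]))
    cls <- if (length(types) > 1L) "multi" else types
    rows <- candidates[candidates$key == p, , drop = FALSE]
    out[[i]] <- data.frame(
      key = p, gene_id = genes, variant_class = cls,
      member_peptides = paste(sort(unique(rows$peptide)), collapse = ";"),
      md5_hits = paste(sort(hit), collapse = ";"),
      samples = paste(sort(unique(rows$sample_id)), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(key = character(0), gene_id = character(0),
                      variant_class = character(0),
                      member_peptides = character(0), md5_hits = character(0),
                      samples = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Merge NRP entries that differ only by missed cleavages
#'
#' Within one gene, two entries are merged when one collapsed peptide is a
#' substring of the other (a missed-cleavage extension) and the two
#' peptides share at least one matching database sequence, i.e. they cover
#' the same variant evidence. Merging is taken to its transitive closure,
#' so the result is independent of input order. The merged key is the
#' shortest member; presence is the union of the members' samples.
#'
#' @param records Output of [map_to_variant_db()].
#' @return Merged data frame of the same shape.
#' @export
merge_missed_cleavages <- function(records) {
  n <- nrow(records)
  if (n <= 1L) return(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  md5_sets <- strsplit(records$md5_hits, ";", fixed = TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (records$gene_id[i] != records$gene_id[j]) next
      a <- records$key[i]; b <- records$key[j]
      sub_rel <- grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)
      if (!sub_rel) next
      if (length(intersect(md5_sets[[i]], md5_sets[[j]])) == 0L) next
      union_(i, j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), root), function(idx) {
    r <- records[idx, , drop = FALSE]
    keys <- r$key
    cls <- unique(r$variant_class)
    data.frame(
      key = keys[order(nchar(keys), keys)][1L],
      gene_id = r$gene_id[1L],
      variant_class = if (length(cls) > 1L) "multi" else cls,
      member_peptides = paste(sort(unique(unlist(
        strsplit(r$member_peptides, ";", fixed = TRUE)))), collapse = ";"),
      md5_hits = paste(sort(unique(unlist(
        strsplit(r$md5_hits, ";", fixed = TRUE)))), collapse = ";"),
      samples = paste(sort(unique(unlist(
        strsplit(r$samples, ";", fixed = TRUE)))), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene_id, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binary NRP presence matrix
#'
#' A cell is 1 iff the NRP was identified and validated in that sample with
#' at least one PSM. Patient breadth is computed through the sample-to-
#' patient map.
#'
#' @param records Merged NRP records.
#' @param samples Character vector fixing the column order.
#' @param patient_map Named character vector: sample id -> patient id.
#' @return List: `matrix` (NRP keys x samples, 0/1) and `n_patients`
#'   (named integer per NRP key).
#' @export
build_presence_matrix <- function(records, samples, patient_map) {
  if (!all(samples %in% names(patient_map))) {
    stop("sample(s) missing from patient_map")
  }
  m <- matrix(0L, nrow = nrow(records), ncol = length(samples),
              dimnames = list(records$key, samples))
  sample_sets <- strsplit(records$samples, ";", fixed = TRUE)
  for (i in seq_len(nrow(records))) {
    pres <- intersect(sample_sets[[i]], samples)
    m[i, pres] <- 1L
  }
  n_pat <- vapply(seq_len(nrow(records)), function(i) {
    length(unique(patient_map[intersect(sample_sets[[i]], samples)]))
  }, integer(1))
  names(n_pat) <- records$key
  list(matrix = m, n_patients = n_pat)
}

#' Restrict NRPs to those detected in a minimum number of patients
#'
#' @param presence Output of [build_presence_matrix()].
#' @param min_patients Minimum patient breadth (default 3).
#' @return The same structure, subset to qualifying NRPs.
#' @export
filter_min_patients <- function(presence, min_patients = 3L) {
  keep <- presence$n_patients >= min_patients
  list(matrix = presence$matrix[keep, , drop = FALSE],
       n_patients = presence$n_patients[keep])
}

#' Run the full NRP calling chain on a cohort
#'
#' Reference subtraction with I/L collapse, cohort-wide mapping to the
#' variant database with the unique-gene rule, missed-cleavage merging,
#' and presence-matrix construction.
#'
#' @param psms Combined PSM table over all samples.
#' @param reference Named character vector of reference proteins.
#' @param db A `cohort_variant_db`.
#' @param samples Sample ids fixing matrix columns.
#' @param patient_map Named sample -> patient map.
#' @param q_max PSM q-value threshold.
#' @return List: `catalog` (merged NRP records with `n_patients`),
#'   `presence` (binary matrix list as in [build_presence_matrix()]).
#' @export
nrp_call <- function(psms, reference, db, samples, patient_map, q_max = 0.01) {
  cand <- filter_nonreference(psms, reference, q_max = q_max)
  recs <- map_to_variant_db(cand, db)
  recs <- merge_missed_cleavages(recs)
  presence <- build_presence_matrix(recs, samples, patient_map)
  recs$n_patients <- unname(presence$n_patients[recs$key])
  list(catalog = recs, presence = presence)
}
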