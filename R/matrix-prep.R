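#' Post-process a raw label-free proteomic intensity matrix
#'
#' Pipeline, in fixed order: log2 transform; artifact removal (log2
#' intensity below `artifact_log2_floor` set to missing); median scale
#' normalisation — each replicate is centred to its own median and the
#' global median (computed over all observed values before centring) is
#' added back; replicates are then averaged per sample, ignoring missing
#' values (a sample value is missing only when all its replicates are).
#'
#' @param raw Numeric matrix proteins x replicates of raw (linear-scale)
#'   intensities; `NA` marks non-detection. All present values must be
#'   positive.
#' @param replicate_map Named character vector: replicate (column) id ->
#'   sample id.
#' @param artifact_log2_floor Artifact threshold on the log2 scale
#'   (default 10, i.e. raw intensity below 1024 is treated as artifact).
#' @return Numeric matrix proteins x samples of normalised log2
#'   intensities with `NA` for missing.
#' @export
preprocess_abundance <- function(raw, replicate_map, artifact_log2_floor = 10) {
  if (any(!is.na(raw) & raw <= 0)) stop("raw intensities must be positive")
  if (!all(colnames(raw) %in% names(replicate_map))) {
    stop("every replicate column must be mapped to a sample")
  }
  x <- log2(raw)
  x[!is.na(x) & x < artifact_log2_floor] <- NA
  global_med <- median(x, na.rm = TRUE)
  x <- apply(x, 2, function(col) col - median(col, na.rm = TRUE) + global_med)
  samples <- unique(unname(replicate_map[colnames(raw)]))
  out <- sapply(samples, function(s) {
    cols <- colnames(raw)[replicate_map[colnames(raw)] == s]
    rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA
  rownames(out) <- rownames(raw)
  colnames(out) <- samples
  out
}

#' Filter proteins by missingness across samples
#'
#' @param mat Proteins x samples matrix with `NA` for missing.
#' @param max_missing_frac Maximum tolerated fraction of missing samples
#'   per protein (default 0.10; the boundary is inclusive).
#' @return The matrix restricted to qualifying proteins.
#' @export
filter_missingness <- function(mat, max_missing_frac = 0.10) {
  frac <- rowMeans(is.na(mat))
  mat[frac <= max_missing_frac, , drop = FALSE]
}

#' Impute left-censored missing values by the stochastic minimal value
#' approach
#'
#' Missing entries of each sample are drawn from a normal distribution
#' centred at a low quantile of that sample's observed values — the model
#' for intensities missing because they fell below the detection limit.
#' The spread is `tune_sigma` times the median over proteins of the
#' per-protein observed standard deviation. Observed cells are never
#' altered; the result is deterministic under `seed`.
#'
#' @param mat Proteins x samples matrix with `NA` for missing.
#' @param q Quantile of each sample's observed values used as the
#'   imputation centre (default 0.02).
#' @param tune_sigma Multiplier on the median per-protein sd (default 1).
#' @param seed Integer seed.
#' @return Complete matrix of the same shape.
#' @export
impute_minprob <- function(mat, q = 0.02, tune_sigma = 1, seed = 1L) {
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 3L)) {
    stop("sample(s) with fewer than 3 observed values: ",
         paste(colnames(mat)[n_obs < 3L], collapse = ", "))
  }
  if (!anyNA(mat)) return(mat)
  prot_sd <- apply(mat, 1, sd, na.rm = TRUE)
  sigma <- tune_sigma * median(prot_sd, na.rm = TRUE)
  out <- mat
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    miss <- which(is.na(mat[, j]))
    if (length(miss) == 0L) next
    mu <- quantile(mat[, j], probs = q, na.rm = TRUE, names = FALSE)
    out[miss, j] <- rnorm(length(miss), mean = mu, sd = sigma)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default RNA-seq quality thresholds
#'
#' Cohort-derived cut-offs: a metric is "good" above the good bound and
#' "poor" at or below the poor bound. Metrics are mRNA content (%),
#' million assigned reads, and percentage of assigned reads.
#'
#' @return List with `good` and `poor` numeric vectors (named `mrna_pct`,
#'   `m_reads`, `assigned_pct`).
#' @export
rna_qc_thresholds <- function() {
  list(good = c(mrna_pct = 76.84, m_reads = 3.6, assigned_pct = 48.3),
       poor = c(mrna_pct = 60, m_reads = 2.3, assigned_pct = 38.9))
}

#' Classify RNA-seq sample quality from three metrics
#'
#' Each metric is rated good (above the good bound), poor (at or below the
#' poor bound) or medium. A sample is `"good"` iff all three metrics are
#' good, `"poor"` iff all three are poor, and `"medium"` otherwise.
#'
#' @param metrics Data frame with columns `mrna_pct`, `m_reads`,
#'   `assigned_pct` (one row per sample).
#' @param thresholds As from [rna_qc_thresholds()].
#' @return Character vector of `"good"`, `"medium"`, `"poor"`.
#' @export
classify_rnaseq_quality <- function(metrics, thresholds = rna_qc_thresholds()) {
  need <- c("mrna_pct", "m_reads", "assigned_pct")
  if (!all(need %in% names(metrics))) stop("missing metric column(s)")
  if (anyNA(metrics[need])) stop("missing metric value(s)")
  rate <- function(x, metric) {
    ifelse(x > thresholds$good[metric], "good",
           ifelse(x <= thresholds$poor[metric], "poor", "medium"))
  }
  r <- cbind(rate(metrics$mrna_pct, "mrna_pct"),
             rate(metrics$m_reads, "m_reads"),
             rate(metrics$assigned_pct, "assigned_pct"))
  unname(apply(r, 1, function(row) {
    if (all(row == "good")) "good" else if (all(row == "poor")) "poor" else "medium"
  }))
}

#' Select one replicate per sample by assigned-read metrics
#'
#' Keeps the replicate maximising (percentage of assigned reads, million
#' assigned reads) lexicographically; ties break to the lexicographically
#' smaller replicate id.
#'
#' @param metrics Data frame with `replicate_id`, `assigned_pct`,
#'   `m_reads`.
#' @return The retained `replicate_id`.
#' @export
select_replicate <- function(metrics) {
  stopifnot(nrow(metrics) >= 1L)
  ord <- order(-metrics$assigned_pct, -metrics$m_reads, metrics$replicate_id)
  metrics$replicate_id[ord[1L]]
}

#' RPKM and TPM normalisation of a transcript count matrix
#'
#' @param counts Non-negative integer matrix transcripts x samples.
#' @param lengths Transcript lengths in bp, aligned to rows.
#' @return List with `rpkm` and `tpm` matrices.
#' @export
normalize_counts <- function(counts, lengths) {
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s)")
  len_kb <- lengths / 1000
  rpkm <- sweep(counts / len_kb, 2, lib / 1e6, "/")
  rate <- counts / len_kb
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  list(rpkm = rpkm, tpm = tpm)
}

#' Filter transcripts by raw-count support
#'
#' Retains transcripts with raw counts strictly above `min_count` in at
#' least `min_frac` of the samples (sample threshold rounded up).
#'
#' @param counts Transcripts x samples count matrix.
#' @param min_count Exclusive count threshold (default 9).
#' @param min_frac Minimum fraction of samples (default 0.30).
#' @return Logical vector over rows (`TRUE` = retained).
#' @export
filter_transcripts <- function(counts, min_count = 9, min_frac = 0.30) {
  need <- ceiling(min_frac * ncol(counts))
  rowSums(counts > min_count) >= need
}

#' Restrict analysis samples by tumour content
#'
#' Samples with tumour content below `min_content` percent are removed;
#' samples without an annotation are excluded with a warning.
#'
#' @param sample_meta Data frame with `sample_id` and `tumour_content`.
#' @param min_content Inclusive lower bound in percent (default 60).
#' @return Character vector of retained sample ids.
#' @export
filter_tumour_content <- function(sample_meta, min_content = 60) {
  missing <- is.na(sample_meta$tumour_content)
  if (any(missing)) {
    warning(sum(missing), " sample(s) without tumour content excluded")
  }
  sample_meta$sample_id[!missing & sample_meta$tumour_content >= min_content]
}
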