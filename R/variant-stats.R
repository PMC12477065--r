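#' Classify a variant by reference-population allele frequency
#'
#' Variants absent from the reference population (no AF record, or AF of
#' exactly zero) are `"novel"`; variants detected in more than
#' `frequent_threshold` of the reference population are `"frequent"`;
#' variants detected at a frequency in `(0, frequent_threshold]` are
#' `"removed"` — too rare to be called frequent but too uncertain to be
#' called disease-linked.
#'
#' @param af Numeric vector of allele frequencies; `NA` means absent from
#'   the reference population.
#' @param frequent_threshold AF cut (default 0.01, i.e. 1%).
#' @return Character vector: `"novel"`, `"frequent"` or `"removed"`.
#' @examples
#' classify_af(c(NA, 0.05, 0.01, 0))
#' @export
classify_af <- function(af, frequent_threshold = 0.01) {
  stopifnot(frequent_threshold > 0, frequent_threshold < 1)
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("AF outside [0,1]")
  ifelse(is.na(af) | af == 0, "novel",
         ifelse(af > frequent_threshold, "frequent", "removed"))
}

#' Test genes for an excess of novel over frequent mutations
#'
#' For each gene with at least one novel or frequent mutation, a one-sided
#' exact binomial test asks whether the gene's novel count exceeds what the
#' reference-population ratio of novel to frequent mutations predicts. The
#' expected proportion is `p0 = r0 / (1 + r0)`, where `r0` is the reference
#' novel:frequent ratio — pooled over all genes by default, or the mean of
#' per-gene ratios.
#'
#' @param tallies Data frame with columns `gene_id`, `n_novel`,
#'   `n_frequent`.
#' @param ref_tallies Data frame with columns `gene_id`, `n_novel`,
#'   `n_frequent` describing the reference population, or `NULL` when `r0`
#'   is given directly.
#' @param r0 Reference novel:frequent ratio (overrides `ref_tallies`).
#' @param ratio Aggregation of the reference ratio: `"pooled"` (sum of
#'   novel over sum of frequent) or `"mean"` (mean of per-gene ratios over
#'   genes with at least one frequent mutation).
#' @param alpha Significance level on BH-adjusted p-values for flagging.
#' @return `tallies` with `excess_p`, `adj_p` and `flagged` columns; genes
#'   with no mutations are dropped.
#' @export
gene_excess_test <- function(tallies, ref_tallies = NULL, r0 = NULL,
                             ratio = c("pooled", "mean"), alpha = 0.05) {
  ratio <- match.arg(ratio)
  if (is.null(r0)) {
    if (is.null(ref_tallies)) stop("supply ref_tallies or r0")
    if (ratio == "pooled") {
      r0 <- sum(ref_tallies$n_novel) / sum(ref_tallies$n_frequent)
    } else {
      with_freq <- ref_tallies$n_frequent > 0
      r0 <- mean(ref_tallies$n_novel[with_freq] / ref_tallies$n_frequent[with_freq])
    }
  }
  if (is.nan(r0) || r0 < 0) stop("invalid reference ratio")
  p0 <- if (is.infinite(r0)) 1 else r0 / (1 + r0)
  tallies <- tallies[tallies$n_novel + tallies$n_frequent >= 1L, , drop = FALSE]
  tallies$excess_p <- vapply(seq_len(nrow(tallies)), function(i) {
    x <- tallies$n_novel[i]
    n <- x + tallies$n_frequent[i]
    if (p0 >= 1) return(1)
    stats::binom.test(x, n, p = p0, alternative = "greater")$p.value
  }, numeric(1))
  tallies$adj_p <- p.adjust(tallies$excess_p, method = "BH")
  tallies$flagged <- tallies$adj_p < alpha
  rownames(tallies) <- NULL
  tallies
}

#' Aggregate deleteriousness scores over genomic mappings
#'
#' When a peptide maps to several genomic locations, the scaled
#' deleteriousness C-scores computed for the different locations are
#' averaged; a mean scaled score of at least 20 (top 1% most deleterious)
#' flags the variant as potentially deleterious.
#'
#' @param scores Numeric vector of scaled C-scores (may be empty).
#' @param deleterious_min Threshold on the mean (default 20).
#' @return List: `mean_score` (`NA` when no score supplied) and
#'   `deleterious` (logical).
#' @export
aggregate_cadd <- function(scores, deleterious_min = 20) {
  if (length(scores) == 0L || all(is.na(scores))) {
    return(list(mean_score = NA_real_, deleterious = FALSE))
  }
  m <- mean(scores, na.rm = TRUE)
  list(mean_score = m, deleterious = m >= deleterious_min)
}

#' Summarise an annotated NRP catalogue
#'
#' @param catalog NRP catalogue with columns `key`, `variant_class`,
#'   `n_patients`, and optionally `af_class` and `deleterious`.
#' @return List: `per_nrp` (the catalogue with a `breadth_bin` column),
#'   `by_class`, `by_breadth` (count tables), `mean_breadth`.
#' @export
summarize_catalog <- function(catalog) {
  bins <- cut(catalog$n_patients, breaks = c(0, 2, 5, 10, Inf),
              labels = c("1-2 patients", "3-5 patients",
                         "6-10 patients", ">10 patients"))
  catalog$breadth_bin <- as.character(bins)
  list(per_nrp = catalog,
       by_class = table(catalog$variant_class),
       by_breadth = table(bins),
       mean_breadth = mean(catalog$n_patients))
}

#' Annotate SAAV-bearing NRPs with allele frequency and deleteriousness
#'
#' @param catalog NRP catalogue (needs `key`, `gene_id`, a `variant_key`
#'   column naming the underlying variant, or one derivable upstream).
#' @param af_table Data frame `variant_key`, `af`.
#' @param cadd_table Optional data frame `variant_key`, `scaled_score`.
#' @param frequent_threshold Passed to [classify_af()].
#' @return Catalogue with `af`, `af_class`, `cadd_scaled`, `deleterious`.
#' @export
annotate_saav <- function(catalog, af_table, cadd_table = NULL,
                          frequent_threshold = 0.01) {
  af <- af_table$af[match(catalog$variant_key, af_table$variant_key)]
  catalog$af <- af
  catalog$af_class <- classify_af(af, frequent_threshold)
  if (!is.null(cadd_table)) {
    agg <- vapply(catalog$variant_key, function(k) {
      s <- cadd_table$scaled_score[cadd_table$variant_key == k]
      a <- aggregate_cadd(s)
      c(a$mean_score, as.numeric(a$deleterious))
    }, numeric(2))
    catalog$cadd_scaled <- agg[1, ]
    catalog$deleterious <- agg[2, ] == 1
  } else {
    catalog$cadd_scaled <- NA_real_
    catalog$deleterious <- FALSE
  }
  catalog
}
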