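#' Per-protein differential abundance between two sample groups
#'
#' Welch two-sample t-test (default) on log2 intensities, or Wilcoxon
#' rank-sum as an alternative; two-sided p-values with BH adjustment
#' across proteins. Effect is mean(A) - mean(B). Proteins with zero
#' variance in both groups get p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param mat Numeric matrix proteins x samples (complete).
#' @param group_a,group_b Column names (or indices) of the two groups,
#'   each of size >= 2.
#' @param method `"welch"` or `"wilcoxon"`.
#' @param contrast Label stored with the result.
#' @return Data frame: `protein`, `effect`, `p`, `adj_p`, `contrast`.
#' @export
differential_abundance <- function(mat, group_a, group_b,
                                   method = c("welch", "wilcoxon"),
                                   contrast = "A_vs_B") {
  method <- match.arg(method)
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("each group needs >= 2 samples")
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  effect <- ma - mb
  if (method == "welch") {
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    se2 <- va / na + vb / nb
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(t_stat), df)
    degen <- se2 == 0
    p[degen & effect == 0] <- 1
    p[degen & effect != 0] <- 0
  } else {
    p <- vapply(seq_len(nrow(mat)), function(i) {
      if (length(unique(c(a[i, ], b[i, ]))) == 1L) return(1)
      stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value
    }, numeric(1))
  }
  data.frame(protein = rownames(mat), effect = effect, p = p,
             adj_p = p.adjust(p, method = "BH"), contrast = contrast,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proteins specifically upregulated in each cluster
#'
#' A protein is specific to cluster c iff, against every other cluster
#' c', its effect (mean difference) is positive and the BH-adjusted
#' p-value of the c-vs-c' contrast is below `alpha` (adjustment within
#' each pairwise contrast). Clusters with fewer than two samples are
#' excluded from contrasts with a warning.
#'
#' @param mat Proteins x samples matrix.
#' @param assignments Named cluster labels per sample.
#' @param alpha Significance level (default 0.05).
#' @param method Test passed to [differential_abundance()].
#' @return Named list of protein character vectors, one per cluster.
#' @export
cluster_specific_upregulation <- function(mat, assignments, alpha = 0.05,
                                          method = "welch") {
  assignments <- assignments[colnames(mat)]
  clusters <- sort(unique(assignments))
  sizes <- table(assignments)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(clusters)) {
    warning("cluster(s) with < 2 samples excluded from contrasts")
  }
  out <- list()
  for (c1 in usable) {
    ok <- rep(TRUE, nrow(mat))
    for (c2 in setdiff(usable, c1)) {
      da <- differential_abundance(mat,
                                   names(assignments)[assignments == c1],
                                   names(assignments)[assignments == c2],
                                   method = method,
                                   contrast = paste(c1, "vs", c2))
      ok <- ok & da$effect > 0 & da$adj_p < alpha
    }
    out[[as.character(c1)]] <- rownames(mat)[ok]
  }
  out
}

#' One-sided Fisher enrichment of NRP presence in a sample group
#'
#' Tests over-representation of presence within the group via the exact
#' hypergeometric tail on the 2x2 table (presence x group membership).
#'
#' @param presence Binary (0/1 or logical) vector over analysis samples.
#' @param in_group Logical vector over the same samples.
#' @return One-sided (greater) p-value; 1 for an all-zero presence row.
#' @examples
#' fisher_enrichment(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), rep(c(TRUE, FALSE), c(3, 7)))
#' @export
fisher_enrichment <- function(presence, in_group) {
  stopifnot(length(presence) == length(in_group))
  presence <- as.integer(presence != 0)
  if (sum(presence) == 0L) return(1)
  tab <- matrix(c(sum(presence == 1 & in_group), sum(presence == 1 & !in_group),
                  sum(presence == 0 & in_group), sum(presence == 0 & !in_group)),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted running-sum statistic on a ranked gene list: hits
#' increment proportionally to `|score|^weight`, misses decrement
#' uniformly; the enrichment score (ES) is the maximum deviation from
#' zero. Significance comes from gene-label permutation, and NES is the
#' ES divided by the mean |permuted ES| of the same sign. Sets with fewer
#' than `min_size` members in the ranked universe are skipped.
#'
#' @param scores Named numeric vector (gene-level ranking metric, no
#'   missing values); ranking is by decreasing score.
#' @param gene_sets Named list of gene id vectors.
#' @param weight Exponent on |score| for hit increments (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param min_size Minimum members-in-universe per set (default 10).
#' @return Data frame of class `gsea_result`: `set`, `size`, `ES`, `NES`,
#'   `p`, `adj_p`.
#' @export
preranked_gsea <- function(scores, gene_sets, weight = 1, n_perm = 1000,
                           seed = 1L, min_size = 10L) {
  if (anyNA(scores)) stop("ranking metric contains missing values")
  ord <- order(scores, decreasing = TRUE)
  genes <- names(scores)[ord]
  s_abs <- abs(scores[ord])^weight
  n <- length(genes)

  sizes <- vapply(gene_sets, function(g) sum(g %in% genes), integer(1))
  skipped <- names(gene_sets)[sizes < min_size]
  if (length(skipped)) {
    warning("set(s) skipped (fewer than ", min_size, " members in universe): ",
            paste(skipped, collapse = ", "))
  }
  gene_sets <- gene_sets[sizes >= min_size]
  if (length(gene_sets) == 0L) {
    return(structure(data.frame(set = character(0), size = integer(0),
                                ES = numeric(0), NES = numeric(0),
                                p = numeric(0), adj_p = numeric(0)),
                     class = c("gsea_result", "data.frame")))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  res <- lapply(names(gene_sets), function(nm) {
    hit <- genes %in% gene_sets[[nm]]
    nh <- sum(hit)
    es <- running_sum_es(hit, s_abs)
    null_es <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      running_sum_es(h, s_abs)
    }, numeric(1))
    same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- if (length(same_sign) == 0L) 1 / (n_perm + 1) else
      (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
    nes <- if (length(same_sign) == 0L || mean(abs(same_sign)) == 0) NA_real_
           else es / mean(abs(same_sign))
    data.frame(set = nm, size = nh, ES = es, NES = nes, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

# Weighted Kolmogorov-Smirnov-like running sum; returns the deviation of
# maximum magnitude (signed).
running_sum_es <- function(hit, s_abs) {
  nr <- sum(s_abs[hit])
  n_miss <- sum(!hit)
  if (n_miss == 0L) return(1)
  inc <- ifelse(hit, if (nr > 0) s_abs / nr else 1 / sum(hit), -1 / n_miss)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Gene-wise Spearman correlation between protein and RNA abundance
#'
#' Spearman rho (average ranks for ties) per shared gene on pairwise
#' complete sample observations, BH adjustment across genes; a gene is
#' flagged concordant when rho > 0.5 and adjusted p < 0.05.
#'
#' @param protein_mat,rna_mat Matrices genes x samples sharing dimnames.
#' @param min_pairs Minimum complete pairs per gene (default 3).
#' @return Data frame: `gene`, `rho`, `p`, `adj_p`, `concordant`.
#' @export
genewise_spearman <- function(protein_mat, rna_mat, min_pairs = 3L) {
  genes <- intersect(rownames(protein_mat), rownames(rna_mat))
  samples <- intersect(colnames(protein_mat), colnames(rna_mat))
  res <- lapply(genes, function(g) {
    x <- protein_mat[g, samples]; y <- rna_mat[g, samples]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) return(NULL)
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(gene = g, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(gene = character(0), rho = numeric(0), p = numeric(0),
                      adj_p = numeric(0), concordant = logical(0)))
  }
  out$adj_p <- p.adjust(out$p, method = "BH")
  out$concordant <- out$rho > 0.5 & out$adj_p < 0.05
  rownames(out) <- NULL
  out
}

#' Pairwise sample similarity: Pearson on abundance, Jaccard on presence
#'
#' @param abundance Proteins x samples matrix (may contain `NA`; Pearson
#'   uses pairwise complete observations).
#' @param presence Binary NRP x samples matrix.
#' @return List with `pearson` and `jaccard` sample x sample matrices.
#' @export
similarity_matrices <- function(abundance = NULL, presence = NULL) {
  out <- list()
  if (!is.null(abundance)) {
    out$pearson <- stats::cor(abundance, use = "pairwise.complete.obs")
  }
  if (!is.null(presence)) {
    p <- presence != 0
    n <- ncol(p)
    j <- matrix(1, n, n, dimnames = list(colnames(p), colnames(p)))
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        un <- sum(p[, i] | p[, k])
        j[i, k] <- if (un == 0) 1 else sum(p[, i] & p[, k]) / un
      }
    }
    out$jaccard <- j
  }
  out
}
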