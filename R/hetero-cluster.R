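#' Pearson correlation distance between samples
#'
#' `1 - r` on the columns of a matrix. Constant-valued samples have no
#' defined correlation and raise an error naming the sample.
#'
#' @param mat Numeric matrix features x samples (complete).
#' @return Symmetric distance matrix samples x samples.
#' @export
pearson_dist <- function(mat) {
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    stop("constant-valued sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(mat)
  d[d < 0] <- 0
  d
}

#' Partitioning around medoids on a precomputed distance matrix
#'
#' Thin wrapper around [cluster::pam()] (build + swap phases), which is
#' deterministic for a given distance matrix.
#'
#' @param dist_mat Square symmetric non-negative distance matrix.
#' @param k Number of clusters.
#' @return List: `assignments` (named integer vector) and `medoids`
#'   (character).
#' @export
pam_cluster <- function(dist_mat, k) {
  n <- nrow(dist_mat)
  if (k > n) stop("k exceeds number of samples")
  ids <- rownames(dist_mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) {   # degenerate: every point its own medoid, zero cost
    return(list(assignments = setNames(seq_len(n), ids), medoids = ids,
                objective = 0))
  }
  fit <- cluster::pam(stats::as.dist(dist_mat), k = k, diss = TRUE)
  list(assignments = fit$clustering, medoids = fit$medoids,
       objective = fit$objective[["swap"]])
}

#' Consensus clustering parameters
#'
#' @param k_range Candidate cluster counts.
#' @param n_resamples Subsampling repetitions per k.
#' @param sample_frac Fraction of samples drawn per repetition.
#' @param elbow_threshold Minimum relative increase in consensus CDF area
#'   for accepting a larger k.
#' @param quantified_frac_min Minimum fraction of samples a protein must be
#'   quantified in to enter clustering (applied upstream, recorded here).
#' @param seed Integer seed.
#' @return List of class `consensus_params`.
#' @export
consensus_params <- function(k_range = 2:6, n_resamples = 1000,
                             sample_frac = 0.8, elbow_threshold = 0.1,
                             quantified_frac_min = 0.90, seed = 1L) {
  stopifnot(all(k_range >= 2), sample_frac > 0, sample_frac <= 1)
  structure(list(k_range = as.integer(k_range),
                 n_resamples = as.integer(n_resamples),
                 sample_frac = sample_frac,
                 elbow_threshold = elbow_threshold,
                 quantified_frac_min = quantified_frac_min,
                 seed = as.integer(seed)),
            class = "consensus_params")
}

#' Consensus clustering with PAM on Pearson distance
#'
#' For each candidate k, samples are repeatedly subsampled, PAM is run on
#' the Pearson-correlation distance of the subsample, and the consensus
#' index of a sample pair is the fraction of co-samplings in which the
#' pair co-clustered. Final assignments at each k come from PAM on
#' `1 - consensus`. k is chosen from the consensus CDF area curve: the
#' largest k whose relative area increase meets the elbow threshold.
#' Results are invariant to column order (computation uses a canonical
#' sample ordering internally).
#'
#' @param mat Complete numeric matrix features x samples.
#' @param params [consensus_params()].
#' @return Object of class `consensus_result`: `consensus` (list of
#'   matrices per k), `assignments` (list per k), `cdf_area`, `delta_area`,
#'   `chosen_k`, `params`.
#' @export
consensus_cluster <- function(mat, params = consensus_params()) {
  ord <- order(colnames(mat))
  mat <- mat[, ord, drop = FALSE]
  n <- ncol(mat)
  m_sub <- max(2L, floor(params$sample_frac * n))
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    stop("constant-valued sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  full_dist <- pearson_dist(mat)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  consensus <- list(); assignments <- list()
  cdf_area <- numeric(0)
  for (k in params$k_range) {
    if (k >= n) stop("k_range contains k >= number of samples")
    set.seed(params$seed + k)     # per-k stream, independent of column order
    hits <- matrix(0, n, n); tries <- matrix(0, n, n)
    for (b in seq_len(params$n_resamples)) {
      idx <- sort(sample.int(n, m_sub))
      cl <- tryCatch(
        pam_cluster(full_dist[idx, idx, drop = FALSE], k)$assignments,
        error = function(e) NULL)
      if (is.null(cl)) next
      co <- outer(cl, cl, "==") * 1
      hits[idx, idx] <- hits[idx, idx] + co
      tries[idx, idx] <- tries[idx, idx] + 1
    }
    cons <- ifelse(tries > 0, hits / tries, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(mat), colnames(mat))
    kk <- as.character(k)
    consensus[[kk]] <- cons
    assignments[[kk]] <- pam_cluster(1 - cons, k)$assignments
    # area under the empirical CDF of the upper-triangle consensus values
    vals <- sort(cons[upper.tri(cons)])
    cdf_area[kk] <- consensus_cdf_area(vals)
  }
  ks <- as.character(params$k_range)
  delta <- numeric(length(ks)); names(delta) <- ks
  delta[1] <- cdf_area[1]
  if (length(ks) > 1) {
    for (i in 2:length(ks)) {
      delta[i] <- (cdf_area[i] - cdf_area[i - 1]) / cdf_area[i - 1]
    }
  }
  delta <- pmax(delta, 0)
  ok <- which(delta >= params$elbow_threshold)
  chosen_k <- if (length(ok)) params$k_range[max(ok)] else params$k_range[1]
  structure(list(consensus = consensus, assignments = assignments,
                 cdf_area = cdf_area, delta_area = delta,
                 chosen_k = chosen_k, params = params),
            class = "consensus_result")
}

# Area under the empirical CDF of consensus index values on [0, 1].
consensus_cdf_area <- function(vals) {
  xs <- c(0, sort(unique(vals)), 1)
  cdf <- vapply(xs, function(x) mean(vals <= x), numeric(1))
  sum(diff(xs) * cdf[-length(cdf)])
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus clustering over k =",
      paste(x$params$k_range, collapse = ", "), "\n")
  cat("chosen k:", x$chosen_k, "\n")
  cat("delta area:", paste(sprintf("%s=%.3f", names(x$delta_area),
                                   x$delta_area), collapse = "  "), "\n")
  invisible(x)
}
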