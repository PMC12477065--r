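# Independent oracles used across tests. Each is a second, deliberately
# naive implementation of the quantity it checks.

# Brute-force variant-combination oracle: every non-empty subset of the
# (in-frame) variants whose members (i) do not overlap on the reference and
# (ii) span at most window_aa residues from the first affected residue of
# the earliest member.
oracle_combinations <- function(variants, window_aa = 30) {
  n <- nrow(variants)
  if (n == 0) return(list())
  aa_start <- variants$pos %/% 3
  aa_end <- (variants$pos + nchar(variants$ref_allele) - 1) %/% 3
  out <- list()
  for (mask in 1:(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(s) > 1) {
      for (i in seq_along(s)) {
        for (j in seq_along(s)) {
          if (i >= j) next
          a <- s[i]; b <- s[j]
          if (variants$pos[a] < variants$pos[b] + nchar(variants$ref_allele[b]) &&
              variants$pos[b] < variants$pos[a] + nchar(variants$ref_allele[a])) {
            ok <- FALSE
          }
        }
      }
    }
    if (ok && max(aa_end[s]) > min(aa_start[s]) + window_aa - 1) ok <- FALSE
    if (ok) out[[length(out) + 1]] <- sort(s)
  }
  out
}

# In-frame variant rows (SNV, +3 insertion, -3 deletion) at given nt offsets.
make_inframe_variants <- function(pos_nt, type = NULL) {
  n <- length(pos_nt)
  if (is.null(type)) type <- rep("snv", n)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    if (type[i] == "snv") { ref[i] <- "A"; alt[i] <- "G" }
    else if (type[i] == "ins") { ref[i] <- "A"; alt[i] <- "ACCC" }
    else { ref[i] <- "AAAA"; alt[i] <- "A" }
  }
  data.frame(pos = pos_nt, ref_allele = ref, alt_allele = alt,
             stringsAsFactors = FALSE)
}

canon_subsets <- function(subsets) {
  sort(vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# Loop-based GSEA running-sum oracle. The returned value carries a "tied"
# attribute flagging instances where the maximum positive and negative
# deviations have (numerically) equal magnitude — there the sign of the ES
# is not well defined and only its magnitude is comparable.
oracle_es <- function(scores, set, w = 1) {
  ord <- order(scores, decreasing = TRUE)
  g <- names(scores)[ord]
  s <- abs(scores[ord])^w
  hit <- g %in% set
  nr <- sum(s[hit]); nm <- sum(!hit)
  run <- 0; best <- 0; hi <- 0; lo <- 0
  for (i in seq_along(g)) {
    run <- run + if (hit[i]) s[i] / nr else -1 / nm
    if (run > hi) hi <- run
    if (run < lo) lo <- run
    if (abs(run) > abs(best)) best <- run
  }
  structure(unname(best), tied = abs(hi + lo) < 1e-9)
}

# Hypergeometric upper-tail oracle for the one-sided 2x2 Fisher test:
# table rbind(c(a, b), c(c, d)), over-representation of row 1 in column 1.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # row-1 total (presence)
  n_ <- c + d         # row-2 total
  k <- a + c          # column-1 total (group size)
  hi <- min(m, k)
  sum(stats::dhyper(a:hi, m, n_, k))
}

# Exact one-sided binomial upper tail.
oracle_binom_greater <- function(x, n, p) {
  if (x == 0) return(1)
  sum(stats::dbinom(x:n, n, p))
}

# Exhaustive best-k-medoid search (small n).
oracle_pam_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (m in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, m, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
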