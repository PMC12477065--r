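#' Kaplan-Meier estimate with Greenwood confidence interval
#'
#' Product-limit estimator via [survival::survfit()]; the median is the
#' smallest time at which the survival function drops to 0.5 or below
#' (undefined — `NA` — when it never does).
#'
#' @param time Positive survival times (months).
#' @param event 1 = death, 0 = censored.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `curve` (data frame `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper`), `median`, `fit` (the underlying `survfit`).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) >= 1L, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  med_idx <- which(fit$surv <= 0.5)
  med <- if (length(med_idx)) fit$time[min(med_idx)] else NA_real_
  list(curve = curve, median = med, fit = fit)
}

#' Two-group log-rank test
#'
#' @param time,event Survival outcome.
#' @param group Two-level grouping factor.
#' @return List: `chisq` (1 df statistic), `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("log-rank needs >= 2 groups")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_fit$n) - 1L
  list(chisq = unname(sd_fit$chisq),
       p = stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Breslow tie handling
#'
#' Wraps [survival::coxph()]; non-convergence or separation (infinite
#' coefficients) is flagged rather than silently reported.
#'
#' @param time,event Survival outcome.
#' @param covariates Data frame of covariates (numeric or factor).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `cox_fit`: `coef`, `hr`, `ci_lower`, `ci_upper`,
#'   `z`, `p` (each named per covariate term), `converged`, `fit`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(event) < 1L) stop("at least one event required")
  dat <- data.frame(.time = time, .event = event, covariates,
                    check.names = TRUE)
  terms <- setdiff(names(dat), c(".time", ".event"))
  const <- vapply(dat[terms], function(x) length(unique(x)) < 2L, logical(1))
  if (any(const)) stop("constant covariate(s): ",
                       paste(terms[const], collapse = ", "))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  nm <- rownames(co)
  iter_max <- if (!is.null(fit$control$iter.max)) fit$control$iter.max else 25L
  converged <- all(is.finite(co[, "coef"])) &&
    all(abs(co[, "coef"]) < 15) && fit$iter[1] < iter_max
  structure(list(coef = setNames(co[, "coef"], nm),
                 hr = setNames(co[, "exp(coef)"], nm),
                 ci_lower = setNames(s$conf.int[, 3], nm),
                 ci_upper = setNames(s$conf.int[, 4], nm),
                 z = setNames(co[, "z"], nm),
                 p = setNames(co[, "Pr(>|z|)"], nm),
                 converged = isTRUE(converged), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  df <- data.frame(coef = x$coef, HR = x$hr, lower = x$ci_lower,
                   upper = x$ci_upper, z = x$z, p = x$p)
  print(round(df, 4))
  if (!x$converged) cat("WARNING: fit flagged as non-converged/separated\n")
  invisible(x)
}

#' Rank proteins by association with overall survival
#'
#' Metastasis-level abundances are collapsed to one value per patient
#' (mean over that patient's samples) to remove pseudo-replication before
#' a univariate Cox fit per protein. Proteins are ranked by the signed
#' Wald z statistic, descending: a positive score means higher abundance
#' in patients with shorter survival, matching the convention that a
#' positive enrichment score downstream indicates upregulation with
#' shorter OS.
#'
#' @param mat Proteins x samples matrix (complete or near-complete).
#' @param records Data frame `patient_id`, `time`, `event` (one row per
#'   patient).
#' @param patient_map Named sample -> patient map.
#' @param max_missing_frac_patients Proteins missing in more than this
#'   fraction of patients are excluded with a warning (default 0.5).
#' @return Data frame sorted by decreasing `z`: `protein`, `z`, `p`.
#' @export
rank_genes_by_survival <- function(mat, records, patient_map,
                                   max_missing_frac_patients = 0.5) {
  pats <- intersect(unique(patient_map[colnames(mat)]), records$patient_id)
  pm <- sapply(pats, function(p) {
    cols <- colnames(mat)[patient_map[colnames(mat)] == p]
    rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
  })
  pm[is.nan(pm)] <- NA
  ri <- match(pats, records$patient_id)
  time <- records$time[ri]; event <- records$event[ri]
  miss <- rowMeans(is.na(pm))
  if (any(miss > max_missing_frac_patients)) {
    warning(sum(miss > max_missing_frac_patients),
            " protein(s) excluded: missing in too many patients")
  }
  keep <- which(miss <= max_missing_frac_patients)
  res <- lapply(keep, function(i) {
    x <- pm[i, ]
    ok <- !is.na(x)
    fit <- tryCatch(
      cox_fit(time[ok], event[ok], data.frame(x = x[ok])),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(protein = rownames(pm)[i], z = unname(fit$z["x"]),
               p = unname(fit$p["x"]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  out <- out[is.finite(out$z), , drop = FALSE]
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-sample signature scores from a z-scored expression matrix
#'
#' The score of a sample for a signature is the mean z-score over the
#' signature genes present in the matrix; signatures with fewer than
#' `min_genes` present yield `NA`.
#'
#' @param zmat Genes x samples matrix, z-scored per gene.
#' @param marker_sets Named list of gene id vectors.
#' @param min_genes Minimum signature genes present (default 3).
#' @return Samples x signatures numeric matrix.
#' @export
signature_score <- function(zmat, marker_sets, min_genes = 3L) {
  out <- sapply(marker_sets, function(g) {
    g <- intersect(g, rownames(zmat))
    if (length(g) < min_genes) return(rep(NA_real_, ncol(zmat)))
    colMeans(zmat[g, , drop = FALSE], na.rm = TRUE)
  })
  rownames(out) <- colnames(zmat)
  out
}

#' Kruskal-Wallis comparison of signature scores across clusters
#'
#' @param scores Samples x signatures matrix from [signature_score()].
#' @param assignments Named cluster labels per sample.
#' @return Data frame `signature`, `chisq`, `p`.
#' @export
signature_cluster_test <- function(scores, assignments) {
  cl <- assignments[rownames(scores)]
  res <- lapply(colnames(scores), function(sig) {
    ok <- !is.na(scores[, sig]) & !is.na(cl)
    kt <- stats::kruskal.test(scores[ok, sig], factor(cl[ok]))
    data.frame(signature = sig, chisq = unname(kt$statistic),
               p = kt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify patients by their dominant proteomic clusters
#'
#' A patient is dominated by the target clusters iff strictly more than
#' half of their clustered metastases fall into them; exactly half counts
#' as `"other"`. Patients without any clustered metastasis are excluded.
#'
#' @param assignments Named cluster labels per sample.
#' @param patient_map Named sample -> patient map.
#' @param target_clusters Cluster labels forming the dominant group
#'   (e.g. `c(1, 3)`).
#' @return Named character vector per patient: `"dominant"` or `"other"`.
#' @export
majority_cluster_class <- function(assignments, patient_map, target_clusters) {
  samples <- names(assignments)
  pats <- unique(unname(patient_map[samples]))
  pats <- pats[!is.na(pats)]
  out <- vapply(pats, function(p) {
    cl <- assignments[samples[patient_map[samples] == p]]
    cl <- cl[!is.na(cl)]
    if (length(cl) == 0L) return(NA_character_)
    if (mean(cl %in% target_clusters) > 0.5) "dominant" else "other"
  }, character(1))
  out[!is.na(out)]
}
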