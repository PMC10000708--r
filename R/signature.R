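#' Random-forest contribution filter for DEGs
#'
#' Trains a random-forest classifier of the TME group labels on the
#' candidate genes (features = genes, log2(TPM+1)) and keeps the genes whose
#' out-of-bag permutation importance (mean decrease in accuracy) clears the
#' retention rule. This drops DEGs that carry little information about the
#' TME grouping before the prognostic screen.
#'
#' @param m An [expression_matrix()] restricted to the candidate genes.
#' @param labels TME group per sample (>= 2 levels; >= 10 samples).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @param rule `"importance_gt_zero"` (default) keeps genes with positive
#'   permutation importance; `"top_n"` keeps the `top_n` highest.
#' @param top_n Number kept under the `"top_n"` rule.
#' @return Character vector of retained gene IDs, with an `importance`
#'   attribute (named numeric vector, all candidates).
#' @export
rf_importance_filter <- function(m, labels, n_trees = 500, seed = 1,
                                 rule = c("importance_gt_zero", "top_n"),
                                 top_n = 100) {
  rule <- match.arg(rule)
  vals <- unclass(log2_transform(m))
  if (!is.null(names(labels))) labels <- labels[colnames(vals)]
  if (length(labels) != ncol(vals) || anyNA(labels)) {
    abort("`labels` must provide one group per sample.")
  }
  if (length(unique(labels)) < 2L) abort("need at least 2 groups.")
  if (ncol(vals) < 10L) abort("need at least 10 samples.")
  x <- t(vals)
  colnames(x) <- rownames(vals)
  y <- factor(labels)
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, importance = TRUE))
  imp <- randomForest::importance(fit, type = 1L, scale = FALSE)[, 1L]
  keep <- switch(rule,
    importance_gt_zero = names(imp)[imp > 0],
    top_n = names(sort(imp, decreasing = TRUE))[seq_len(min(top_n, length(imp)))]
  )
  structure(keep, importance = imp)
}

#' Univariate Cox prognostic filter
#'
#' Retains genes whose log2(TPM+1) expression is associated with overall
#' survival in a univariate Cox model (Wald p < `alpha`). This is the
#' "influences the prognosis" screen applied to TME-group DEGs before gene
#' clustering.
#'
#' @param m An [expression_matrix()] restricted to candidate genes.
#' @param clinical Clinical tibble (see [validate_clinical_table()]) covering
#'   the matrix's samples.
#' @param alpha Wald p-value threshold (default 0.05).
#' @return Character vector of retained gene IDs, with a `cox_table`
#'   attribute (tibble of gene, coef, hr, wald_p).
#' @export
prognostic_filter <- function(m, clinical, alpha = 0.05) {
  clinical <- validate_clinical_table(clinical)
  vals <- unclass(log2_transform(m))
  idx <- match(colnames(vals), clinical$sample_id)
  if (anyNA(idx)) abort("clinical table lacks some matrix samples.")
  time <- clinical$os_time[idx]
  event <- clinical$os_event[idx]
  if (sum(event) == 0) abort("no events in the clinical table.")
  res <- purrr::map_dfr(rownames(vals), function(g) {
    x <- vals[g, ]
    if (stats::sd(x) == 0) {
      return(tibble(gene_id = g, coef = NA_real_, hr = NA_real_,
                    wald_p = 1))
    }
    fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
    s <- summary(fit)$coefficients
    tibble(gene_id = g, coef = s[1, "coef"], hr = exp(s[1, "coef"]),
           wald_p = s[1, "Pr(>|z|)"])
  })
  keep <- res$gene_id[res$wald_p < alpha]
  structure(keep, cox_table = res)
}

#' Split signature genes into adverse (A) and favorable (B) sets
#'
#' Given the k = 2 gene clusters (from gene-based consensus clustering) and
#' a k = 2 sample partition on the same genes, determines which sample group
#' has the poorer prognosis (sign of the Cox coefficient of the group
#' indicator) and anchors gene set A to the gene cluster whose mean
#' expression is higher in that poorer-prognosis group; set B is the other
#' cluster. This fixes the orientation of the TMEscore so that high scores
#' track the favorable gene program.
#'
#' @param m An [expression_matrix()] restricted to the signature genes.
#' @param gene_clusters Named vector in \{1, 2\}: gene cluster per gene.
#' @param sample_groups Named vector in \{1, 2\}: sample partition (e.g.
#'   k-means on the same genes).
#' @param clinical Clinical tibble with survival for the samples.
#' @return List: `set_a`, `set_b` (gene-ID vectors), `orientation_note`,
#'   `poor_group`.
#' @export
split_signature_sets <- function(m, gene_clusters, sample_groups, clinical) {
  vals <- unclass(log2_transform(m))
  if (nrow(vals) < 2L) abort("need at least 2 genes to split.")
  gene_clusters <- gene_clusters[rownames(vals)]
  if (anyNA(gene_clusters)) abort("`gene_clusters` must cover all genes.")
  if (length(unique(gene_clusters)) != 2L) {
    abort("`gene_clusters` must define exactly 2 non-empty clusters.")
  }
  if (!is.null(names(sample_groups))) sample_groups <- sample_groups[colnames(vals)]
  clinical <- validate_clinical_table(clinical)
  idx <- match(colnames(vals), clinical$sample_id)
  if (anyNA(idx)) abort("clinical table lacks some matrix samples.")
  grp2 <- as.integer(sample_groups == sort(unique(sample_groups))[2L])
  fit <- survival::coxph(
    survival::Surv(clinical$os_time[idx], clinical$os_event[idx]) ~ grp2,
    ties = "efron")
  poor_group <- if (unname(stats::coef(fit)) > 0) {
    sort(unique(sample_groups))[2L]
  } else {
    sort(unique(sample_groups))[1L]
  }
  cl_ids <- sort(unique(gene_clusters))
  mean_in_poor <- vapply(cl_ids, function(cl) {
    mean(vals[gene_clusters == cl, sample_groups == poor_group, drop = FALSE])
  }, numeric(1))
  a_cl <- cl_ids[which.max(mean_in_poor)]
  set_a <- rownames(vals)[gene_clusters == a_cl]
  set_b <- rownames(vals)[gene_clusters != a_cl]
  list(
    set_a = set_a, set_b = set_b,
    orientation_note = sprintf(
      "set A = gene cluster %s (mean log2 expression %.2f vs %.2f in poorer-prognosis sample group %s)",
      a_cl, max(mean_in_poor), min(mean_in_poor), poor_group),
    poor_group = poor_group
  )
}

#' Compute the TMEscore
#'
#' Per sample, `TMEscore = TMEscoreB - TMEscoreA`, where each component is
#' the [ssgsea_score()] of the corresponding signature gene set. By default
#' the raw ssGSEA scores are subtracted (two like-scaled quantities); set
#' `normalize = TRUE` to unity-normalize each component across samples
#' first.
#'
#' @param m An [expression_matrix()] (full gene universe).
#' @param set_a,set_b Signature gene-ID vectors (disjoint).
#' @param alpha ssGSEA weight (default 0.25).
#' @param normalize Unity-normalize components before subtracting?
#' @return Tibble: `sample_id`, `tmescore_a`, `tmescore_b`, `tmescore`.
#' @export
compute_tmescore <- function(m, set_a, set_b, alpha = 0.25,
                             normalize = FALSE) {
  if (length(intersect(set_a, set_b)) &&
      !setequal(set_a, set_b)) {
    abort("`set_a` and `set_b` must be disjoint.")
  }
  e <- ssgsea_matrix(m, list(A = set_a, B = set_b), alpha = alpha)
  if (nrow(e) < 2L) abort("both signature sets must intersect the genes.")
  if (normalize) e <- unity_normalize(e)
  v <- unclass(e)
  tibble(
    sample_id = colnames(v),
    tmescore_a = unname(v["A", ]),
    tmescore_b = unname(v["B", ]),
    tmescore = unname(v["B", ] - v["A", ])
  )
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every admissible cutpoint on a continuous score — midpoints between
#' consecutive distinct values whose induced high/low groups each hold at
#' least `ceiling(min_prop * n)` samples — computes the standardized
#' log-rank statistic |Z| for the induced two-group split, and returns the
#' cutpoint maximizing |Z| (ties broken toward the smaller cutpoint). The
#' selected split's log-rank p-value, if reported downstream without
#' selection correction, is anti-conservative; the cutpoint is used for
#' stratification, not inference.
#'
#' @param score Numeric per-sample score.
#' @param time,event Survival outcome (see [km_estimate()]).
#' @param min_prop Minimum fraction of samples on each side (default 0.1).
#' @return List: `cutpoint`, `max_statistic` (|Z|), `n_candidates`, and
#'   `scan` (tibble of candidate cutpoints and |Z|).
#' @export
maxstat_cutpoint <- function(score, time, event, min_prop = 0.1) {
  check_surv_input(time, event)
  if (length(score) != length(time)) abort("`score` length must match `time`.")
  if (sum(event) < 1) abort("need at least one event.")
  if (min_prop <= 0 || min_prop >= 0.5) abort("`min_prop` must be in (0, 0.5).")
  n <- length(score)
  min_n <- ceiling(min_prop * n)
  s <- sort(unique(score))
  if (length(s) < 2L) abort("score is constant; no admissible cutpoint.")
  mids <- (s[-1L] + s[-length(s)]) / 2
  n_low <- vapply(mids, function(c) sum(score <= c), integer(1))
  ok <- n_low >= min_n & (n - n_low) >= min_n
  if (!any(ok)) abort("no admissible cutpoint under `min_prop`.")
  mids <- mids[ok]
  z <- vapply(mids, function(c) abs(logrank_z(time, event, score > c)),
              numeric(1))
  best <- which(z == max(z, na.rm = TRUE))[1L] # sorted mids: first = smallest
  list(cutpoint = mids[best], max_statistic = z[best],
       n_candidates = length(mids),
       scan = tibble(cutpoint = mids, abs_z = z))
}

# standardized log-rank statistic Z = (O1 - E1)/sqrt(V) for a binary split
logrank_z <- function(time, event, in_high) {
  o <- order(time)
  time <- time[o]
  event <- event[o]
  g <- in_high[o]
  ev_times <- unique(time[event == 1])
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    O <- O + d1
    E <- E + d * n1 / n_t
    if (n_t > 1) {
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

#' Fit the full TME signature model
#'
#' Convenience wrapper producing the package's fitted artifact: given the
#' derived gene sets and a cohort, computes per-sample TMEscores, finds the
#' maxstat cutpoint against survival, and labels samples high/low.
#'
#' @param m An [expression_matrix()].
#' @param set_a,set_b Signature gene sets (A = adverse, B = favorable).
#' @param clinical Clinical tibble for the cohort.
#' @param alpha ssGSEA weight.
#' @param min_prop Maxstat admissibility fraction.
#' @param orientation_note Free-text record of how A/B were oriented.
#' @return A `tme_signature` object: `set_a`, `set_b`, `alpha`, `scores`
#'   (tibble with `risk_label`), `cutpoint`, `max_statistic`,
#'   `orientation_note`.
#' @export
fit_tme_signature <- function(m, set_a, set_b, clinical, alpha = 0.25,
                              min_prop = 0.1, orientation_note = "") {
  clinical <- validate_clinical_table(clinical)
  sc <- compute_tmescore(m, set_a, set_b, alpha = alpha)
  idx <- match(sc$sample_id, clinical$sample_id)
  if (anyNA(idx)) abort("clinical table lacks some matrix samples.")
  ms <- maxstat_cutpoint(sc$tmescore, clinical$os_time[idx],
                         clinical$os_event[idx], min_prop = min_prop)
  sc$risk_label <- ifelse(sc$tmescore > ms$cutpoint, "high", "low")
  structure(
    list(set_a = set_a, set_b = set_b, alpha = alpha, scores = sc,
         cutpoint = ms$cutpoint, max_statistic = ms$max_statistic,
         orientation_note = orientation_note),
    class = "tme_signature"
  )
}

#' Score a new cohort with a frozen signature model
#'
#' Applies the signature's gene sets and stored cutpoint to a new expression
#' matrix without re-deriving anything. Genes absent from the new cohort are
#' dropped from the sets with a reported coverage fraction; the run aborts
#' if less than half of either set is covered.
#'
#' @param model A `tme_signature`.
#' @param m An [expression_matrix()] for the new cohort.
#' @param min_coverage Minimum fraction of each set that must be present.
#' @return Tibble: `sample_id`, `tmescore_a`, `tmescore_b`, `tmescore`,
#'   `risk_label` (vs the frozen cutpoint).
#' @export
score_cohort <- function(model, m, min_coverage = 0.5) {
  stopifnot(inherits(model, "tme_signature"))
  genes <- rownames(m)
  a <- intersect(model$set_a, genes)
  b <- intersect(model$set_b, genes)
  cov_a <- length(a) / length(model$set_a)
  cov_b <- length(b) / length(model$set_b)
  if (cov_a < min_coverage || cov_b < min_coverage) {
    abort(sprintf("signature coverage too low (A: %.0f%%, B: %.0f%%).",
                  100 * cov_a, 100 * cov_b))
  }
  if (cov_a < 1 || cov_b < 1) {
    inform(sprintf("signature coverage: set A %.0f%%, set B %.0f%%.",
                   100 * cov_a, 100 * cov_b))
  }
  sc <- compute_tmescore(m, a, b, alpha = model$alpha)
  sc$risk_label <- ifelse(sc$tmescore > model$cutpoint, "high", "low")
  sc
}

#' @export
print.tme_signature <- function(x, ...) {
  cat(sprintf(
    "<tme_signature> |A| = %d, |B| = %d, alpha = %.2f, cutpoint = %.4f (|Z| = %.2f)\n",
    length(x$set_a), length(x$set_b), x$alpha, x$cutpoint, x$max_statistic))
  if (nzchar(x$orientation_note)) cat(" ", x$orientation_note, "\n")
  print(table(risk = x$scores$risk_label))
  invisible(x)
}

#' Tidy a TME signature model
#' @param x A `tme_signature`.
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @export
tidy.tme_signature <- function(x, ...) x$scores

#' @export
glance.tme_signature <- function(x, ...) {
  tibble(
    n_set_a = length(x$set_a), n_set_b = length(x$set_b),
    n_samples = nrow(x$scores), alpha = x$alpha,
    cutpoint = x$cutpoint, max_statistic = x$max_statistic,
    n_high = sum(x$scores$risk_label == "high"),
    n_low = sum(x$scores$risk_label == "low")
  )
}

#' Distribution of TMEscores by risk group
#' @param object A `tme_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tme_signature <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$tmescore, fill = .data$risk_label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = 2) +
    ggplot2::labs(x = "TMEscore", y = "samples", fill = "risk") +
    ggplot2::theme_minimal()
}

#' Serialize / restore a signature model as JSON
#'
#' @param model A `tme_signature`.
#' @param path Output path.
#' @return `path` invisibly; `read_tme_signature()` returns the model (the
#'   per-sample training scores are not stored).
#' @export
write_tme_signature <- function(model, path) {
  stopifnot(inherits(model, "tme_signature"))
  obj <- list(set_a = model$set_a, set_b = model$set_b, alpha = model$alpha,
              cutpoint = model$cutpoint, max_statistic = model$max_statistic,
              orientation_note = model$orientation_note)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tme_signature
#' @export
read_tme_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(set_a = obj$set_a, set_b = obj$set_b, alpha = obj$alpha,
         scores = NULL, cutpoint = obj$cutpoint,
         max_statistic = obj$max_statistic,
         orientation_note = obj$orientation_note %||% ""),
    class = "tme_signature"
  )
}
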