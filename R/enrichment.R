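#' Single-sample GSEA enrichment score for one sample
#'
#' Computes the integral-form ssGSEA statistic for one gene set in one
#' sample. Genes are ranked within the sample (highest expression gets rank
#' N; ties get the average rank) and walked in decreasing-rank order. In-set
#' genes contribute weighted steps \eqn{r_g^\alpha / \sum_{g \in S}
#' r_g^\alpha} to the in-set empirical CDF; out-of-set genes contribute
#' uniform steps \eqn{1/(N-m)}. The score is the sum over all N positions of
#' the difference between the two running CDFs — the integral of the running
#' deviation, not the maximum deviation used by classic GSEA. Because only
#' within-sample ranks enter, the score is invariant to any strictly
#' increasing transform of the expression column.
#'
#' @param expr Named numeric vector: expression of all genes in one sample.
#' @param gene_set Character vector of gene IDs; must intersect `names(expr)`
#'   but not cover it entirely.
#' @param alpha Rank-weighting exponent (default 0.25, the conventional
#'   ssGSEA weight).
#' @return A single numeric enrichment score.
#' @export
#' @examples
#' expr <- c(A = 4, B = 3, C = 2, D = 1)
#' ssgsea_score(expr, "A") # 2
#' ssgsea_score(expr, "D") # -2
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) abort("`expr` must be a named vector.")
  check_scalar_number(alpha, "alpha", lower = 0)
  in_set <- names(expr) %in% gene_set
  m <- sum(in_set)
  n <- length(expr)
  if (m == 0L) abort("gene set does not intersect the gene universe.")
  if (m == n) abort("gene set covers the whole gene universe.")
  r <- rank(expr, ties.method = "average")
  ord <- order(r, seq_along(r), decreasing = TRUE) # ties: input gene order
  ssgsea_from_ranks(r, ord, in_set, alpha)
}

# shared kernel: score from precomputed ranks/ordering
# sum_j cum_j = sum_i step_i * (N - pos_i + 1), so no explicit cumsum needed
ssgsea_from_ranks <- function(r, ord, in_set, alpha) {
  n <- length(r)
  m <- sum(in_set)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  tail_len <- n - pos + 1L
  w <- r[in_set]^alpha
  sum((r[in_set]^alpha / sum(w)) * tail_len[in_set]) -
    sum(tail_len[!in_set]) / (n - m)
}

#' ssGSEA scores for a gene-set collection across samples
#'
#' Applies [ssgsea_score()] to every (set, sample) pair. Sets that do not
#' intersect the gene universe are dropped with a warning; per-sample ranks
#' are computed once and reused across sets.
#'
#' @param m An [expression_matrix()] (any unit; only within-sample ranks are
#'   used) or a named numeric matrix.
#' @param sets Named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return An `enrichment_matrix`: sets x samples numeric matrix with a
#'   `normalized = FALSE` attribute.
#' @export
ssgsea_matrix <- function(m, sets, alpha = 0.25) {
  check_named_matrix(unclass(m), "m")
  if (!length(sets) || is.null(names(sets))) abort("`sets` must be a named list.")
  genes <- rownames(m)
  inter <- lapply(sets, intersect, x = genes)
  # intersect(x = genes, y = set) keeps universe order; size checks below
  sizes <- lengths(inter)
  drop <- sizes == 0L | sizes == nrow(m)
  if (all(drop)) abort("no gene set has a usable intersection with the matrix.")
  if (any(drop)) {
    warn(sprintf("dropping %d set(s) with empty or full gene-universe overlap: %s",
                 sum(drop), paste(names(sets)[drop], collapse = ", ")))
  }
  sets <- sets[!drop]
  memb <- vapply(sets, function(s) genes %in% s, logical(nrow(m)))
  vals <- unclass(m)
  scores <- vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(r, seq_along(r), decreasing = TRUE)
    vapply(seq_along(sets), function(k) {
      ssgsea_from_ranks(r, ord, memb[, k], alpha)
    }, numeric(1))
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(names(sets), colnames(vals)))
  enrichment_matrix(scores, normalized = FALSE)
}

#' Enrichment matrix container
#'
#' @param scores Numeric set-by-sample matrix with dimnames.
#' @param normalized Logical: has per-row unity normalization been applied?
#' @return An `enrichment_matrix` object.
#' @export
enrichment_matrix <- function(scores, normalized = FALSE) {
  check_named_matrix(scores, "scores")
  structure(scores, normalized = isTRUE(normalized),
            class = c("enrichment_matrix", "matrix", "array"))
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> %d sets x %d samples [%s]\n",
              nrow(x), ncol(x),
              if (attr(x, "normalized")) "unity-normalized" else "raw"))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

#' Tidy an enrichment matrix into long format
#' @param x An `enrichment_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `set_name`, `sample_id`, `score`,
#'   `normalized`.
#' @export
tidy.enrichment_matrix <- function(x, ...) {
  tibble(
    set_name = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    score = as.vector(unclass(x)),
    normalized = attr(x, "normalized")
  )
}

#' Unity-normalize an enrichment matrix
#'
#' Rescales every row (cell type / gene set) linearly so its minimum is 0 and
#' its maximum is 1 across samples. A constant row carries no between-sample
#' information and is set to all zeros with a warning. Normalizing twice is
#' the same as normalizing once.
#'
#' @param e An `enrichment_matrix`.
#' @return A unity-normalized `enrichment_matrix`.
#' @export
unity_normalize <- function(e) {
  check_named_matrix(unclass(e), "e")
  v <- unclass(e)
  rmin <- apply(v, 1L, min)
  rmax <- apply(v, 1L, max)
  rng <- rmax - rmin
  const <- rng == 0
  if (any(const)) {
    warn(sprintf("constant enrichment row(s) set to zero: %s",
                 paste(rownames(v)[const], collapse = ", ")))
    rng[const] <- 1 # avoid 0/0; numerator is 0 for these rows
  }
  out <- (v - rmin) / rng
  enrichment_matrix(out, normalized = TRUE)
}

#' ESTIMATE-style stromal/immune scores and tumor purity
#'
#' Scores each sample's stromal and immune infiltration with [ssgsea_score()]
#' on the two provided gene sets, sums them into a combined infiltration
#' score, and converts that score to a tumor-purity estimate with the cosine
#' calibration of the ESTIMATE method:
#' \eqn{purity = \cos(c_0 + c_1 \cdot score)}, clamped to \[0, 1\]. The
#' default constants are the published calibration; they were fitted against
#' ABSOLUTE purities on TCGA Affymetrix data, so treat purity values from
#' other platforms as relative orderings rather than calibrated fractions.
#'
#' @param m An [expression_matrix()].
#' @param stromal_set,immune_set Character vectors of gene IDs.
#' @param alpha ssGSEA weight (default 0.25).
#' @param c0,c1 Cosine calibration constants (published defaults).
#' @return A tibble with columns `sample_id`, `stromal_score`,
#'   `immune_score`, `estimate_score`, `purity`.
#' @export
estimate_purity <- function(m, stromal_set, immune_set, alpha = 0.25,
                            c0 = 0.6049872018, c1 = 0.0001467884) {
  e <- ssgsea_matrix(m, list(stromal = stromal_set, immune = immune_set),
                     alpha = alpha)
  if (nrow(e) < 2L) abort("both stromal and immune sets must intersect the genes.")
  est <- unclass(e)["stromal", ] + unclass(e)["immune", ]
  purity <- pmin(1, pmax(0, cos(c0 + c1 * est)))
  tibble(
    sample_id = colnames(e),
    stromal_score = unname(unclass(e)["stromal", ]),
    immune_score = unname(unclass(e)["immune", ]),
    estimate_score = unname(est),
    purity = unname(purity)
  )
}

#' Preranked GSEA with a gene-permutation null
#'
#' Classic (max-deviation) GSEA on a preranked gene-level statistic. The
#' running sum increases by \eqn{|s_g|^p / \sum_{g \in S} |s_g|^p} at in-set
#' genes and decreases by \eqn{1/(N-m)} at out-of-set genes, walking genes in
#' decreasing-statistic order; the enrichment score (ES) is the running sum's
#' maximum deviation from zero, signed. The null distribution comes from
#' `n_perm` random gene-label permutations (equivalently, random sets of the
#' same size); NES divides ES by the mean |null ES| of matching sign, and the
#' permutation p-value is the one-sided tail frequency among matching-sign
#' nulls with +1 smoothing.
#'
#' @param gene_stats Named numeric vector of per-gene ranking statistics
#'   (e.g. from [score_to_gene_ranking()]).
#' @param gene_set Character vector of gene IDs.
#' @param p Weighting exponent (default 1; `p = 0` gives the unweighted
#'   Kolmogorov–Smirnov running statistic).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param null_sets Optional list of explicit null gene-ID sets to use
#'   instead of random permutations (e.g. an exhaustive enumeration on a toy
#'   problem); overrides `n_perm`.
#' @return A one-row tibble: `set_name`, `es`, `nes`, `p_perm`, `n_perm`,
#'   `size`, and a list-column `leading_edge` of the in-set genes at or
#'   before the ES extremum.
#' @export
preranked_gsea <- function(gene_stats, gene_set, p = 1, n_perm = 1000,
                           seed = 1, null_sets = NULL) {
  if (is.null(names(gene_stats))) abort("`gene_stats` must be named.")
  if (any(!is.finite(gene_stats))) abort("`gene_stats` must be finite.")
  genes <- names(gene_stats)
  n <- length(genes)
  in_set <- genes %in% gene_set
  m <- sum(in_set)
  if (m == 0L || m == n) abort("gene set must be a proper non-empty subset.")
  ord <- order(gene_stats, seq_len(n), decreasing = TRUE)
  es_of <- function(memb) gsea_es(gene_stats, ord, memb, p)
  obs <- es_of(in_set)
  if (!is.null(null_sets)) {
    null_es <- vapply(null_sets, function(s) es_of(genes %in% s)$es,
                      numeric(1))
  } else {
    if (n_perm < 1L) abort("`n_perm` must be >= 1.")
    null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      memb <- logical(n)
      memb[sample.int(n, m)] <- TRUE
      es_of(memb)$es
    }, numeric(1)))
  }
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same) && mean(abs(same)) > 0) obs$es / mean(abs(same)) else NA_real_
  p_perm <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  tibble(
    set_name = "set", es = obs$es, nes = nes, p_perm = p_perm,
    n_perm = length(null_es), size = m,
    leading_edge = list(obs$leading_edge)
  )
}

# weighted running-sum ES: returns signed max deviation + leading edge
gsea_es <- function(stats, ord, memb, p) {
  n <- length(stats)
  m <- sum(memb)
  s_ord <- stats[ord]
  memb_ord <- memb[ord]
  w <- abs(s_ord)^p
  hit <- ifelse(memb_ord, w, 0)
  tot <- sum(hit)
  if (tot == 0) {
    # all in-set stats are zero at p > 0: fall back to uniform in-set steps
    hit <- as.numeric(memb_ord) / m
  } else {
    hit <- hit / tot
  }
  run <- cumsum(hit - (1 - memb_ord) / (n - m))
  i_max <- which.max(abs(run))
  es <- unname(run[i_max])
  le <- if (es >= 0) {
    names(s_ord)[seq_len(i_max)][memb_ord[seq_len(i_max)]]
  } else {
    names(s_ord)[i_max:n][memb_ord[i_max:n]]
  }
  list(es = es, leading_edge = le)
}

#' Gene-level ranking statistic from a per-sample score
#'
#' Correlates every gene's log2(TPM+1) expression with a per-sample score
#' (Pearson), producing the gene-level statistic that feeds
#' [preranked_gsea()] when samples are ranked by TMEscore. Genes with zero
#' variance get statistic 0.
#'
#' @param m An [expression_matrix()].
#' @param score Named (or matrix-ordered) numeric vector, one value per
#'   sample; must not be constant. Needs at least 3 samples.
#' @return Named numeric vector of per-gene correlations.
#' @export
score_to_gene_ranking <- function(m, score) {
  vals <- unclass(log2_transform(m))
  if (ncol(vals) < 3L) abort("need at least 3 samples.")
  if (!is.null(names(score))) score <- score[colnames(vals)]
  if (length(score) != ncol(vals) || anyNA(score)) {
    abort("`score` must provide one value per sample.")
  }
  if (stats::sd(score) == 0) abort("`score` is constant.")
  sds <- apply(vals, 1L, stats::sd)
  out <- rep(0, nrow(vals))
  ok <- sds > 0
  if (any(ok)) {
    out[ok] <- as.vector(stats::cor(t(vals[ok, , drop = FALSE]), score))
  }
  setNames(out, rownames(vals))
}
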