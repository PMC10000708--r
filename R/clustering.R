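#' Consensus clustering by resampling
#'
#' Monti-style consensus clustering: repeatedly subsample items (and
#' optionally features), run a base clusterer at a fixed `k`, and record for
#' every item pair how often the two items land in the same cluster among
#' the resamples containing both. The consensus matrix entry (i, j) is that
#' co-clustering fraction; final labels come from average-linkage
#' hierarchical clustering of `1 - consensus` cut at `k`.
#'
#' The defaults mirror the sample-subtyping configuration used throughout
#' the package: 1000 resamples at 80% item sampling, all features, with
#' complete-linkage hierarchical clustering on Manhattan distances as the
#' base clusterer. For gene clustering the conventional base is
#' `"hclust_wardD2_euclidean"`.
#'
#' @param data Item-by-feature numeric matrix (items in rows, with
#'   rownames).
#' @param k Number of clusters, `2 <= k <= nrow(data)`.
#' @param reps Number of resampling repetitions (>= 1).
#' @param p_item Fraction of items drawn (without replacement) per rep.
#' @param p_feature Fraction of features drawn per rep.
#' @param base Base clusterer: `"hclust_complete_manhattan"`,
#'   `"hclust_wardD2_euclidean"`, or `"kmeans_euclidean"`.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return A `consensus_result`: list with `k`, `consensus` (item x item
#'   matrix in \[0,1\]), `labels` (named integer vector), `cdf_area`,
#'   `co_sample_counts`, `reps`.
#' @export
consensus_cluster <- function(data, k, reps = 1000, p_item = 0.8,
                              p_feature = 1.0,
                              base = c("hclust_complete_manhattan",
                                       "hclust_wardD2_euclidean",
                                       "kmeans_euclidean"),
                              seed = 1) {
  base <- match.arg(base)
  if (is.null(rownames(data))) rownames(data) <- paste0("item", seq_len(nrow(data)))
  n <- nrow(data)
  if (k < 2L || k > n) abort("`k` must satisfy 2 <= k <= nrow(data).")
  if (reps < 1L) abort("`reps` must be >= 1.")
  if (p_item <= 0 || p_item > 1) abort("`p_item` must be in (0, 1].")
  n_item <- ceiling(p_item * n)
  n_feat <- max(1L, ceiling(p_feature * ncol(data)))
  if (n_item < k) abort("subsample smaller than k; increase p_item.")

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      items <- if (n_item == n) seq_len(n) else sort(sample.int(n, n_item))
      feats <- if (n_feat == ncol(data)) seq_len(ncol(data)) else
        sort(sample.int(ncol(data), n_feat))
      lab <- base_cluster(data[items, feats, drop = FALSE], k, base)
      co_sample[items, items] <- co_sample[items, items] + 1
      same <- outer(lab, lab, "==") * 1
      co_cluster[items, items] <- co_cluster[items, items] + same
    }
  })
  consensus <- matrix(0, n, n)
  seen <- co_sample > 0
  consensus[seen] <- co_cluster[seen] / co_sample[seen]
  if (any(!seen[upper.tri(seen)])) {
    warn("some item pairs were never co-sampled; their consensus is set to 0.")
  }
  dimnames(consensus) <- dimnames(co_sample) <- list(rownames(data), rownames(data))

  labels <- stats::cutree(
    stats::hclust(stats::as.dist(1 - consensus), method = "average"), k = k)
  off <- consensus[upper.tri(consensus)]
  structure(
    list(k = as.integer(k), consensus = consensus,
         labels = setNames(as.integer(labels), rownames(data)),
         cdf_area = consensus_cdf_area(off),
         pac = mean(off > 0.1 & off < 0.9),
         co_sample_counts = co_sample, reps = as.integer(reps)),
    class = "consensus_result"
  )
}

# base clusterers behind consensus resampling
base_cluster <- function(x, k, base) {
  switch(base,
    hclust_complete_manhattan = stats::cutree(
      stats::hclust(stats::dist(x, method = "manhattan"), method = "complete"), k),
    hclust_wardD2_euclidean = stats::cutree(
      stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2"), k),
    kmeans_euclidean = if (k == nrow(x)) {
      # every item its own cluster; stats::kmeans requires k < n
      seq_len(nrow(x))
    } else {
      stats::kmeans(x, centers = k, nstart = 10)$cluster
    }
  )
}

# area under the empirical CDF of off-diagonal consensus values over [0,1]
consensus_cdf_area <- function(v) {
  if (!length(v)) return(0)
  xs <- sort(unique(c(0, v, 1)))
  cdf <- stats::ecdf(v)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = %d, %d items, %d reps, CDF area %.3f\n",
              x$k, length(x$labels), x$reps, x$cdf_area))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Tidy a consensus result
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return Tibble with `item`, `cluster`.
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(item = names(x$labels), cluster = x$labels)
}

#' @export
glance.consensus_result <- function(x, ...) {
  tibble(k = x$k, n_items = length(x$labels), reps = x$reps,
         cdf_area = x$cdf_area,
         mean_within_consensus = {
           same <- outer(x$labels, x$labels, "==")
           mean(x$consensus[same & upper.tri(same)])
         },
         mean_between_consensus = {
           same <- outer(x$labels, x$labels, "==")
           mb <- x$consensus[!same & upper.tri(same)]
           if (length(mb)) mean(mb) else NA_real_
         })
}

#' Heatmap of a consensus matrix
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- names(sort(object$labels))
  df <- tibble(
    item_i = factor(rep(rownames(object$consensus), times = ncol(object$consensus)),
                    levels = ord),
    item_j = factor(rep(colnames(object$consensus), each = nrow(object$consensus)),
                    levels = ord),
    consensus = as.vector(object$consensus)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$item_i, .data$item_j,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c5aa0",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus",
                  title = sprintf("Consensus matrix, k = %d", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Choose the number of clusters from consensus CDF areas
#'
#' Computes, for each `k`, the area under the empirical CDF of off-diagonal
#' consensus values, the relative delta-area
#' \eqn{\Delta(k) = (A(k) - A(k-1)) / A(k-1)} for `k >= 3`, and the
#' proportion of ambiguous clustering (PAC: the fraction of consensus
#' entries strictly between 0.1 and 0.9). The chosen `k` is the largest one
#' whose relative delta-area exceeds `threshold` *and* whose consensus is
#' crisp (PAC at most `pac_max`); when no `k >= 3` qualifies — flat
#' delta-areas or diffuse consensus, i.e. no evidence of structure beyond
#' two clusters — the rule returns 2. The PAC condition is what lets the
#' rule return 2 on structureless data, where CDF areas keep growing with
#' `k` even though no clustering is stable.
#'
#' @param results List of `consensus_result` objects for a contiguous k
#'   range starting at 2 (as from [consensus_sweep()]).
#' @param threshold Relative delta-area threshold (default 0.1).
#' @param pac_max Maximum proportion of ambiguous consensus entries for a
#'   `k` to be considered stable (default 0.2).
#' @return A list: `k` (chosen), `table` (tibble of `k`, `cdf_area`,
#'   `delta_area`, `pac`).
#' @export
select_k <- function(results, threshold = 0.1, pac_max = 0.2) {
  if (length(results) < 2L) abort("need consensus results for at least two k values.")
  ks <- vapply(results, function(r) r$k, integer(1))
  if (any(diff(sort(ks)) != 1L) || min(ks) != 2L) {
    abort("`results` must cover a contiguous k range starting at 2.")
  }
  o <- order(ks)
  ks <- ks[o]
  areas <- vapply(results[o], function(r) r$cdf_area, numeric(1))
  pacs <- vapply(results[o], function(r) r$pac %||% 0, numeric(1))
  delta <- c(NA_real_, diff(areas) / pmax(areas[-length(areas)], .Machine$double.eps))
  ok <- delta[-1L] > threshold & pacs[-1L] <= pac_max
  candidates <- ks[-1L][ok]
  chosen <- if (length(candidates)) max(candidates) else 2L
  list(k = as.integer(chosen),
       table = tibble(k = ks, cdf_area = areas, delta_area = delta,
                      pac = pacs))
}

#' Run consensus clustering over a range of k
#'
#' @inheritParams consensus_cluster
#' @param k_range Integer vector of k values (contiguous, starting at 2).
#' @return Named list of `consensus_result` objects (`"k2"`, `"k3"`, ...).
#' @export
consensus_sweep <- function(data, k_range = 2:5, reps = 1000, p_item = 0.8,
                            p_feature = 1.0,
                            base = "hclust_complete_manhattan", seed = 1) {
  res <- lapply(k_range, function(k) {
    consensus_cluster(data, k, reps = reps, p_item = p_item,
                      p_feature = p_feature, base = base,
                      seed = derive_seed(seed, k))
  })
  names(res) <- paste0("k", k_range)
  res
}

#' K-means clustering with multiple restarts
#'
#' Thin wrapper over [stats::kmeans()] (Hartigan–Wong) that fixes the random
#' stream, uses `n_init` random restarts, and returns the best partition by
#' within-cluster sum of squares.
#'
#' @param data Numeric matrix, items in rows.
#' @param k Number of clusters.
#' @param n_init Number of random restarts.
#' @param seed Integer seed.
#' @return Named integer vector of cluster labels.
#' @export
kmeans_cluster <- function(data, k, n_init = 10, seed = 1) {
  if (k > nrow(data)) abort("`k` exceeds the number of items.")
  nms <- rownames(data) %||% as.character(seq_len(nrow(data)))
  if (k == nrow(data)) {
    # each item its own cluster with zero within-cluster SSE
    return(setNames(seq_len(nrow(data)), nms))
  }
  fit <- with_seed(seed, stats::kmeans(data, centers = k, nstart = n_init))
  setNames(as.integer(fit$cluster), nms)
}

#' Hierarchical clustering with a chosen metric and linkage
#'
#' @param data Numeric matrix, items in rows.
#' @param k Number of clusters to cut.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param linkage `"complete"`, `"wardD2"`, or `"average"`.
#' @return List with `labels` (named integer vector) and `tree` (the
#'   `hclust` object).
#' @export
hclust_cluster <- function(data, k, metric = c("euclidean", "manhattan"),
                           linkage = c("complete", "wardD2", "average")) {
  metric <- match.arg(metric)
  linkage <- switch(match.arg(linkage),
                    complete = "complete", wardD2 = "ward.D2",
                    average = "average")
  if (k > nrow(data)) abort("`k` exceeds the number of items.")
  tree <- stats::hclust(stats::dist(data, method = metric), method = linkage)
  labels <- stats::cutree(tree, k = k)
  list(labels = setNames(as.integer(labels),
                         rownames(data) %||% as.character(seq_len(nrow(data)))),
       tree = tree)
}
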