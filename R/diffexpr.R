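#' Empirical-Bayes moderated two-group t-test
#'
#' Gene-wise two-group comparison on log2(TPM + 1) expression with variance
#' moderation. For each gene the log2 fold change is `mean(group B) -
#' mean(group A)` and the pooled residual variance \eqn{s_g^2} has
#' \eqn{d = n_A + n_B - 2} degrees of freedom. A scaled inverse-chi-square
#' prior \eqn{(d_0, s_0^2)} is estimated by matching the moments of
#' \eqn{\log s_g^2} (closed-form method-of-moments with trigamma inversion);
#' the posterior variance \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s_g^2)/(d_0 +
#' d)} replaces \eqn{s_g^2} in the t-statistic, which is referred to a t
#' distribution on \eqn{d_0 + d} degrees of freedom. P-values are BH
#' adjusted, and `passes_filter` marks genes with `|log2fc| > lfc_thr` and
#' `adj_p < alpha` (both strict, the conventional DEG definition here).
#'
#' @param m An [expression_matrix()] (TPM or FPKM; log2-transformed
#'   internally) or an already-LOG2 matrix.
#' @param group_labels Vector with exactly two distinct values, one per
#'   sample (in matrix column order, or named by sample). The
#'   lexicographically first value is group A.
#' @param lfc_thr Absolute log2-fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param d0_override Optional prior degrees of freedom: `0` disables
#'   moderation (ordinary pooled t), `Inf` fully shrinks every variance to
#'   the prior.
#' @return A `deg_table` tibble: `gene_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `t_stat`, `p_value`, `adj_p`, `passes_filter`, with attributes `d0`,
#'   `s0_sq`, `groups`.
#' @export
moderated_t_test <- function(m, group_labels, lfc_thr = 1, alpha = 0.05,
                             d0_override = NULL) {
  vals <- unclass(log2_transform(m))
  if (!is.null(names(group_labels))) group_labels <- group_labels[colnames(vals)]
  if (length(group_labels) != ncol(vals) || anyNA(group_labels)) {
    abort("`group_labels` must provide one label per sample.")
  }
  lv <- sort(unique(as.character(group_labels)))
  if (length(lv) != 2L) abort("`group_labels` must have exactly two levels.")
  ia <- group_labels == lv[1L]
  ib <- group_labels == lv[2L]
  na <- sum(ia)
  nb <- sum(ib)
  if (na < 2L || nb < 2L) abort("each group needs at least 2 samples.")

  mean_a <- rowMeans(vals[, ia, drop = FALSE])
  mean_b <- rowMeans(vals[, ib, drop = FALSE])
  log2fc <- mean_b - mean_a
  d <- na + nb - 2L
  ss <- rowSums((vals[, ia, drop = FALSE] - mean_a)^2) +
    rowSums((vals[, ib, drop = FALSE] - mean_b)^2)
  s2 <- ss / d

  if (is.null(d0_override)) {
    prior <- fit_var_prior(s2, d)
  } else {
    check_d0 <- d0_override
    if (!(is.numeric(check_d0) && length(check_d0) == 1L && check_d0 >= 0)) {
      abort("`d0_override` must be a single number >= 0 (Inf allowed).")
    }
    s0 <- if (is.finite(d0_override) && d0_override == 0) NA_real_ else
      fit_var_prior(s2, d)$s0_sq
    prior <- list(d0 = d0_override, s0_sq = s0)
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_stat <- ifelse(se > 0, log2fc / se, 0)
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p <- pmax(p, .Machine$double.xmin)
  adj <- bh_adjust(p)
  out <- tibble(
    gene_id = rownames(vals),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2fc = unname(log2fc), t_stat = unname(t_stat),
    p_value = unname(p), adj_p = unname(adj),
    passes_filter = abs(log2fc) > lfc_thr & adj < alpha
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "groups") <- lv
  class(out) <- c("deg_table", class(out))
  out
}

# method-of-moments fit of the scaled inverse-chi-square variance prior:
# log s_g^2 given s0^2 is log-F distributed; match mean/variance of
# e_g = log s_g^2 - digamma(d/2) + log(d/2)
fit_var_prior <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: variances look exchangeable
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x on y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and returned in
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' One-vs-rest differential expression across k groups
#'
#' Runs [moderated_t_test()] of each group against all remaining samples and
#' collects the genes passing the DEG filter per group (direction recorded),
#' plus the pairwise overlap counts of the per-group DEG sets.
#'
#' @param m An [expression_matrix()].
#' @param multi_labels Group label per sample (>= 2 levels, each with >= 2
#'   samples).
#' @param lfc_thr,alpha Filter thresholds as in [moderated_t_test()].
#' @return A list: `tables` (named list of `deg_table`s, one per group, with
#'   log2fc oriented as group-minus-rest), `deg_sets` (named list of gene-ID
#'   vectors), `overlap` (group x group matrix of DEG-set intersections).
#' @export
one_vs_rest_degs <- function(m, multi_labels, lfc_thr = 1, alpha = 0.05) {
  vals <- unclass(m)
  if (!is.null(names(multi_labels))) multi_labels <- multi_labels[colnames(vals)]
  groups <- sort(unique(as.character(multi_labels)))
  if (length(groups) < 2L) abort("need at least 2 groups.")
  tabs <- lapply(groups, function(g) {
    lab <- ifelse(multi_labels == g, "b_group", "a_rest")
    if (sum(lab == "b_group") < 2L) {
      abort(sprintf("group '%s' has fewer than 2 samples.", g))
    }
    moderated_t_test(m, lab, lfc_thr = lfc_thr, alpha = alpha)
  })
  names(tabs) <- groups
  sets <- lapply(tabs, function(t) t$gene_id[t$passes_filter])
  overlap <- outer(seq_along(sets), seq_along(sets),
                   Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(overlap) <- list(groups, groups)
  list(tables = tabs, deg_sets = sets, overlap = overlap)
}

#' @export
glance.deg_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_deg = sum(x$passes_filter),
    n_up = sum(x$passes_filter & x$log2fc > 0),
    n_down = sum(x$passes_filter & x$log2fc < 0),
    d0 = attr(x, "d0"),
    s0_sq = attr(x, "s0_sq")
  )
}

#' Volcano plot of a DEG table
#' @param object A `deg_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$log2fc, -log10(.data$adj_p),
                                       colour = .data$passes_filter)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "DEG") +
    ggplot2::theme_minimal()
}
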