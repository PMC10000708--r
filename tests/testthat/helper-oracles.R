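# Independent oracle implementations used to cross-check the package.
# These are written with explicit loops and textbook formulas on purpose;
# they must stay independent of the code paths they check.

# ssGSEA integral statistic, gene by gene, no vectorization
naive_ssgsea <- function(expr, gene_set, alpha = 0.25) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(r, seq_along(r), decreasing = TRUE)
  in_set <- names(expr) %in% gene_set
  m <- sum(in_set)
  denom <- 0
  for (i in which(in_set)) denom <- denom + r[i]^alpha
  cum_in <- 0
  cum_out <- 0
  score <- 0
  for (pos in seq_len(n)) {
    g <- ord[pos]
    if (in_set[g]) {
      cum_in <- cum_in + r[g]^alpha / denom
    } else {
      cum_out <- cum_out + 1 / (n - m)
    }
    score <- score + (cum_in - cum_out)
  }
  unname(score)
}

# classic unweighted KS running statistic (signed max deviation)
naive_ks_es <- function(stats_vec, gene_set) {
  n <- length(stats_vec)
  ord <- order(stats_vec, seq_len(n), decreasing = TRUE)
  in_set <- names(stats_vec) %in% gene_set
  m <- sum(in_set)
  run <- 0
  best <- 0
  for (pos in seq_len(n)) {
    g <- ord[pos]
    run <- run + if (in_set[g]) 1 / m else -1 / (n - m)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# weighted (|stat|^p) running-sum ES, explicit loop
naive_weighted_es <- function(stats_vec, gene_set, p = 1) {
  n <- length(stats_vec)
  ord <- order(stats_vec, seq_len(n), decreasing = TRUE)
  in_set <- names(stats_vec) %in% gene_set
  m <- sum(in_set)
  denom <- 0
  for (g in which(in_set)) denom <- denom + abs(stats_vec[g])^p
  run <- 0
  best <- 0
  for (pos in seq_len(n)) {
    g <- ord[pos]
    run <- run + if (in_set[g]) abs(stats_vec[g])^p / denom else -1 / (n - m)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# log-rank chi-square from a hand-tabulated O/E/V table
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  ev_times <- sort(unique(time[event == 1]))
  O <- 0
  E <- 0
  V <- 0
  for (t in ev_times) {
    at <- time >= t
    n_t <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n_t
    if (n_t > 1) V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  list(O = O, E = E, V = V, chi2 = (O - E)^2 / V)
}

# brute-force maxstat scan using survival::survdiff as the log-rank engine
oracle_maxstat <- function(score, time, event, min_prop = 0.1) {
  n <- length(score)
  min_n <- ceiling(min_prop * n)
  s <- sort(unique(score))
  mids <- (s[-1L] + s[-length(s)]) / 2
  best_cut <- NA_real_
  best_z <- -Inf
  for (cut in mids) {
    lo <- sum(score <= cut)
    if (lo < min_n || (n - lo) < min_n) next
    g <- factor(score > cut)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    z <- sqrt(sd$chisq)
    if (z > best_z + 1e-12) {
      best_z <- z
      best_cut <- cut
    }
  }
  list(cutpoint = best_cut, max_statistic = best_z)
}

# ordinary pooled-variance two-sample t on each row of a log2 matrix
oracle_pooled_t <- function(log2_mat, is_b) {
  out <- matrix(NA_real_, nrow(log2_mat), 2,
                dimnames = list(rownames(log2_mat), c("t", "p")))
  na <- sum(!is_b)
  nb <- sum(is_b)
  for (i in seq_len(nrow(log2_mat))) {
    xa <- log2_mat[i, !is_b]
    xb <- log2_mat[i, is_b]
    sp2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (na + nb - 2)
    tval <- (mean(xb) - mean(xa)) / sqrt(sp2 * (1 / na + 1 / nb))
    out[i, ] <- c(tval, 2 * stats::pt(-abs(tval), na + nb - 2))
  }
  out
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small random expression fixture with TPM columns
random_tpm <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    v <- matrix(2^stats::rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    fpkm_to_tpm(expression_matrix(v, "FPKM"))
  })
}

# items-by-features matrix with k planted, well-separated groups
planted_feature_matrix <- function(n_items, n_features, k, sep = 10,
                                   noise = 1, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(seq_len(k), length.out = n_items)
    centers <- matrix(stats::rnorm(k * n_features, 0, sep), k, n_features)
    x <- centers[lab, ] + matrix(stats::rnorm(n_items * n_features, 0, noise),
                                 n_items, n_features)
    rownames(x) <- sprintf("item%03d", seq_len(n_items))
    list(x = x, labels = lab)
  })
}
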