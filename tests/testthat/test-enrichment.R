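test_that("ssGSEA reproduces the hand-enumerated 4-gene example", {
  expr <- c(A = 4, B = 3, C = 2, D = 1)
  # set {A}: running differences 1, 2/3, 1/3, 0 sum to 2; {D} mirrors it
  expect_equal(ssgsea_score(expr, "A"), 2)
  expect_equal(ssgsea_score(expr, "D"), -2)
  expect_error(ssgsea_score(expr, "Z"), "intersect")
  expect_error(ssgsea_score(expr, c("A", "B", "C", "D")), "whole")
})

test_that("ssGSEA is invariant to strictly increasing transforms", {
  for (seed in 1:5) {
    expr <- withr::with_seed(seed, setNames(stats::rexp(50), paste0("g", 1:50)))
    set <- paste0("g", c(3, 7, 20, 41))
    s0 <- ssgsea_score(expr, set)
    expect_equal(ssgsea_score(log1p(expr), set), s0, tolerance = 1e-12)
    expect_equal(ssgsea_score(expr^3, set), s0, tolerance = 1e-12)
    expect_equal(ssgsea_score(10 + 2 * expr, set), s0, tolerance = 1e-12)
  }
})

test_that("the vectorized matrix scorer agrees with the naive loop oracle", {
  m <- random_tpm(100, 20, seed = 7)
  sets <- withr::with_seed(8, lapply(1:6, function(i) {
    sample(rownames(m), sample(5:20, 1))
  }))
  names(sets) <- paste0("set", 1:6)
  e <- ssgsea_matrix(m, sets)
  for (s in names(sets)) {
    for (j in seq_len(ncol(m))) {
      expect_equal(unclass(e)[s, j],
                   naive_ssgsea(unclass(m)[, j], sets[[s]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("matrix scoring composes per column and drops unusable sets", {
  m <- random_tpm(30, 3, seed = 3)
  sets <- list(good = rownames(m)[1:5], empty = c("nope1", "nope2"))
  expect_warning(e <- ssgsea_matrix(m, sets), "dropping")
  expect_equal(nrow(e), 1L)
  expect_equal(unclass(e)["good", 2],
               ssgsea_score(unclass(m)[, 2], sets$good))
  # permuting samples permutes columns identically
  perm <- c(3, 1, 2)
  e2 <- suppressWarnings(ssgsea_matrix(m[, perm], sets))
  expected <- unclass(e)[, perm, drop = FALSE]
  attr(expected, "normalized") <- FALSE
  expect_equal(unclass(e2), expected)
  expect_error(suppressWarnings(ssgsea_matrix(m, list(bad = "nope"))),
               "no gene set")
})

test_that("unity normalization maps rows to [0, 1] and is idempotent", {
  e <- enrichment_matrix(matrix(c(2, 4, 6, 5, 5, 5), 2, 3, byrow = TRUE,
                                dimnames = list(c("a", "const"),
                                                c("s1", "s2", "s3"))))
  expect_warning(n1 <- unity_normalize(e), "constant")
  expect_equal(unname(unclass(n1)["a", ]), c(0, 0.5, 1))
  expect_equal(unname(unclass(n1)["const", ]), c(0, 0, 0))
  expect_true(attr(n1, "normalized"))
  n2 <- suppressWarnings(unity_normalize(n1))
  expect_equal(unclass(n2), unclass(n1))
})

test_that("ESTIMATE-style purity decreases with infiltration", {
  co <- generate_cohort(cohort_config(n_samples = 150, n_genes = 500,
                                      n_cell_types = 6,
                                      genes_per_signature = 8,
                                      n_planted_degs = 10,
                                      infiltration_effect = 2, seed = 13))
  stromal <- co$truth$signature_genes[[1]] # elevated in group 1
  immune <- co$truth$signature_genes[[4]]  # also marks group 1
  pur <- estimate_purity(co$expression, stromal, immune,
                         c1 = 0.002) # steeper slope for the synthetic scale
  expect_true(all(pur$purity >= 0 & pur$purity <= 1))
  expect_equal(pur$estimate_score, pur$stromal_score + pur$immune_score)
  grp <- co$truth$group[pur$sample_id]
  expect_lt(mean(pur$purity[grp == 1]), mean(pur$purity[grp != 1]))
  # cosine calibration is monotone decreasing while its argument stays in (0, pi)
  ord <- order(pur$estimate_score)
  expect_true(all(diff(pur$purity[ord]) <= 1e-12))
})

test_that("preranked GSEA matches known extremes and the exhaustive null", {
  stats_vec <- setNames(seq(3, -3, length.out = 12), paste0("g", 1:12))
  # all set genes at the top with weight 0: maximal deviation of 1
  res <- preranked_gsea(stats_vec, c("g1", "g2", "g3"), p = 0, n_perm = 10,
                        seed = 1)
  expect_equal(res$es, 1)
  expect_setequal(res$leading_edge[[1]], c("g1", "g2", "g3"))

  # weight 0 reduces to the classical unweighted KS statistic
  for (seed in 1:5) {
    sv <- withr::with_seed(seed, setNames(stats::rnorm(30), paste0("g", 1:30)))
    set <- paste0("g", withr::with_seed(seed + 50, sample(30, 7)))
    expect_equal(preranked_gsea(sv, set, p = 0, n_perm = 5, seed = 1)$es,
                 naive_ks_es(sv, set), tolerance = 1e-12)
  }

  # exhaustive 2-subsets of a 6-gene list as the null: ES and p match an
  # independent loop enumeration
  sv <- setNames(c(2.5, 1.4, 0.8, -0.3, -1.1, -2.2), paste0("g", 1:6))
  subsets <- utils::combn(names(sv), 2, simplify = FALSE)
  obs <- preranked_gsea(sv, c("g1", "g2"), p = 1, null_sets = subsets)
  es_exact <- naive_weighted_es(sv, c("g1", "g2"), p = 1)
  expect_equal(obs$es, es_exact, tolerance = 1e-12)
  null_es <- vapply(subsets, function(s) naive_weighted_es(sv, s, p = 1),
                    numeric(1))
  same_sign <- if (es_exact >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p_exact <- (1 + sum(abs(same_sign) >= abs(es_exact))) / (1 + length(same_sign))
  expect_equal(obs$p_perm, p_exact)
  expect_error(preranked_gsea(sv, names(sv), n_perm = 5), "proper")
})

test_that("score-to-gene ranking is a Pearson correlation", {
  m <- random_tpm(40, 12, seed = 5)
  lg <- unclass(log2_transform(m))
  score <- lg["g001", ]
  stat <- score_to_gene_ranking(m, score)
  expect_equal(unname(stat["g001"]), 1)
  stat2 <- score_to_gene_ranking(m, -score)
  expect_equal(unname(stat2["g001"]), -1)
  # direct covariance/SD oracle
  for (g in rownames(m)[1:10]) {
    x <- lg[g, ]
    oracle <- sum((x - mean(x)) * (score - mean(score))) /
      sqrt(sum((x - mean(x))^2) * sum((score - mean(score))^2))
    expect_equal(unname(stat[g]), oracle, tolerance = 1e-12)
  }
  expect_error(score_to_gene_ranking(m, rep(1, ncol(m))), "constant")
})
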