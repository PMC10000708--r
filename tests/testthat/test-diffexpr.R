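test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # monotone: smaller p never gets a larger q
  for (seed in 1:5) {
    p <- withr::with_seed(seed, stats::runif(50))
    q <- bh_adjust(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("without moderation the statistic is the ordinary pooled t", {
  m <- random_tpm(80, 24, seed = 31)
  is_b <- rep(c(FALSE, TRUE), each = 12)
  lab <- ifelse(is_b, "b", "a")
  dt <- moderated_t_test(m, lab, d0_override = 0)
  oracle <- oracle_pooled_t(unclass(log2_transform(m)), is_b)
  expect_equal(dt$t_stat, unname(oracle[, "t"]), tolerance = 1e-10)
  expect_equal(dt$p_value, unname(oracle[, "p"]), tolerance = 1e-10)
})

test_that("infinite prior degrees of freedom shrink every variance to s0^2", {
  m <- random_tpm(60, 20, seed = 32)
  lab <- rep(c("a", "b"), each = 10)
  dt <- moderated_t_test(m, lab, d0_override = 1e8)
  s0 <- attr(dt, "s0_sq")
  expected_t <- dt$log2fc / sqrt(s0 * (1 / 10 + 1 / 10))
  expect_equal(dt$t_stat, expected_t, tolerance = 1e-3)
  dt_inf <- moderated_t_test(m, lab, d0_override = Inf)
  expect_equal(dt_inf$t_stat, dt_inf$log2fc / sqrt(s0 * 0.2), tolerance = 1e-6)
})

test_that("moderation agrees with the reference empirical-Bayes implementation", {
  m <- random_tpm(300, 30, seed = 33)
  is_b <- rep(c(FALSE, TRUE), each = 15)
  dt <- moderated_t_test(m, ifelse(is_b, "b", "a"))
  lg <- unclass(log2_transform(m))
  design <- cbind(1, as.integer(is_b))
  fit <- limma::eBayes(limma::lmFit(lg, design))
  expect_equal(attr(dt, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(dt, "s0_sq"), fit$s2.prior, tolerance = 0.01)
  expect_equal(dt$t_stat, unname(fit$t[, 2]), tolerance = 0.02)
  expect_gt(stats::cor(dt$p_value, unname(fit$p.value[, 2])), 0.9999)
})

test_that("equal group means give zero fold change and null-like p-values", {
  # construct a LOG2 matrix whose group means are exactly equal per gene
  base <- withr::with_seed(34, matrix(stats::rnorm(40 * 8, 6, 1), 40, 8))
  lg <- cbind(base, base) # group B duplicates group A column-wise
  dimnames(lg) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:16))
  m <- expression_matrix(lg, "LOG2")
  dt <- moderated_t_test(m, rep(c("a", "b"), each = 8))
  expect_equal(dt$log2fc, rep(0, 40))
  expect_equal(dt$t_stat, rep(0, 40))
  expect_false(any(dt$passes_filter))
})

test_that("planted DEGs are recovered at the standard thresholds", {
  co <- generate_cohort(cohort_config(n_samples = 80, n_genes = 800,
                                      n_groups = 2,
                                      group_proportions = c(0.5, 0.5),
                                      n_cell_types = 4,
                                      genes_per_signature = 5,
                                      infiltration_effect = 0,
                                      n_planted_degs = 30, deg_log2fc = 2,
                                      seed = 35))
  lab <- ifelse(co$truth$group == 1, "g1", "g2")
  dt <- moderated_t_test(co$expression, lab)
  planted <- co$truth$deg_table$gene_id
  sens <- mean(planted %in% dt$gene_id[dt$passes_filter])
  fp <- setdiff(dt$gene_id[dt$passes_filter], planted)
  expect_gte(sens, 0.9)
  expect_lte(length(fp) / (nrow(dt) - length(planted)), 0.02)
})

test_that("one-vs-rest at k = 2 mirrors a single two-group test", {
  co <- generate_cohort(cohort_config(n_samples = 60, n_genes = 300,
                                      n_groups = 2,
                                      group_proportions = c(0.5, 0.5),
                                      n_cell_types = 4,
                                      genes_per_signature = 5,
                                      n_planted_degs = 20, seed = 36))
  ovr <- one_vs_rest_degs(co$expression, co$truth$group)
  expect_setequal(ovr$deg_sets[["1"]], ovr$deg_sets[["2"]])
  t1 <- ovr$tables[["1"]]
  t2 <- ovr$tables[["2"]]
  expect_equal(t1$log2fc, -t2$log2fc, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  expect_equal(ovr$overlap["1", "2"], length(ovr$deg_sets[["1"]]))
})

test_that("group-specific planted genes give disjoint one-vs-rest DEG sets", {
  co <- generate_cohort(cohort_config(n_samples = 120, n_genes = 600,
                                      n_cell_types = 6,
                                      genes_per_signature = 6,
                                      infiltration_effect = 0,
                                      n_planted_degs = 30, deg_log2fc = 3,
                                      seed = 37))
  ovr <- one_vs_rest_degs(co$expression, co$truth$group)
  planted_by_group <- split(co$truth$deg_table$gene_id,
                            co$truth$deg_table$group)
  for (g in names(planted_by_group)) {
    tab <- ovr$tables[[g]]
    up <- tab$gene_id[tab$passes_filter & tab$log2fc > 0]
    expect_gte(mean(planted_by_group[[g]] %in% up), 0.85)
  }
  # a gene planted up in one group can only leak into other groups as a
  # DOWN-regulated call, so the up-regulated DEG sets are disjoint
  up_sets <- lapply(ovr$tables, function(t) {
    t$gene_id[t$passes_filter & t$log2fc > 0]
  })
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_length(intersect(up_sets[[i]], up_sets[[j]]), 0)
    }
  }
})

test_that("the fold-change threshold is strict", {
  # one gene with an exact log2 difference of 1 and zero within-group
  # variance (the moderated variance keeps its t finite)
  lg <- withr::with_seed(38, matrix(stats::rnorm(30 * 12, 5, 1), 30, 12))
  lg[1, ] <- c(rep(5, 6), rep(6, 6))
  dimnames(lg) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12))
  dt <- moderated_t_test(expression_matrix(lg, "LOG2"),
                         rep(c("a", "b"), each = 6))
  expect_identical(dt$log2fc[1], 1)
  # |log2FC| > 1 is strict: a gene sitting exactly on the boundary is excluded
  # no matter how significant its p-value is
  expect_false(dt$passes_filter[1])
})
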