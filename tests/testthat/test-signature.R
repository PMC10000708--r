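test_that("random-forest filter keeps informative genes and drops noise", {
  withr::with_seed(71, {
    n <- 150
    grp <- rep(c("g1", "g2"), each = n / 2)
    inf <- matrix(stats::rnorm(30 * n, 6, 1), 30, n)
    inf[, grp == "g2"] <- inf[, grp == "g2"] + 4
    noise <- matrix(stats::rnorm(300 * n, 6, 1), 300, n)
    lg <- rbind(inf, noise)
    dimnames(lg) <- list(c(sprintf("inf%02d", 1:30), sprintf("ns%03d", 1:300)),
                         sprintf("s%03d", 1:n))
    m <- expression_matrix(lg, "LOG2")
  })
  kept <- rf_importance_filter(m, grp, n_trees = 300, seed = 72)
  informative <- sprintf("inf%02d", 1:30)
  expect_gte(mean(informative %in% kept), 0.9)
  expect_gte(mean(!(sprintf("ns%03d", 1:300) %in% kept)), 0.8)
  # a zero-variance gene has zero permutation importance and is dropped
  lg2 <- rbind(lg, flat = rep(5, n))
  kept2 <- rf_importance_filter(expression_matrix(lg2, "LOG2"), grp,
                                n_trees = 100, seed = 73)
  expect_false("flat" %in% kept2)
  expect_error(rf_importance_filter(m, rep("g1", n)), "2 groups")
})

test_that("the prognostic filter is powered for real effects and calibrated under the null", {
  withr::with_seed(74, {
    n <- 200
    x_prog <- stats::rnorm(n)                       # true log-hazard 1 per unit
    time <- stats::rexp(n, 0.05 * exp(1 * x_prog))
    null_mat <- matrix(stats::rnorm(100 * n, 6, 1), 100, n)
    lg <- rbind(prog = x_prog + 6, null_mat)
    dimnames(lg) <- list(c("prog", sprintf("n%03d", 1:100)),
                         sprintf("s%03d", 1:n))
  })
  clin <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         os_time = time, os_event = 1)
  m <- expression_matrix(lg, "LOG2")
  kept <- prognostic_filter(m, clin)
  expect_true("prog" %in% kept)
  # null genes retained near the nominal 5% rate
  null_rate <- mean(sprintf("n%03d", 1:100) %in% kept)
  expect_lt(null_rate, 0.12)
  expect_length(prognostic_filter(m, clin, alpha = 0), 0)
  expect_error(prognostic_filter(m, dplyr::mutate(clin, os_event = 0)),
               "no events")
})

test_that("signature sets split along planted blocks with prognosis-anchored orientation", {
  withr::with_seed(75, {
    n <- 120
    sgrp <- rep(c(1, 2), each = n / 2) # sample partition
    # block A genes high in sample group 1, block B genes high in group 2
    blkA <- matrix(stats::rnorm(10 * n, 5, 0.5), 10, n) +
      2 * matrix(rep(sgrp == 1, each = 10), 10, n)
    blkB <- matrix(stats::rnorm(10 * n, 5, 0.5), 10, n) +
      2 * matrix(rep(sgrp == 2, each = 10), 10, n)
    lg <- rbind(blkA, blkB)
    dimnames(lg) <- list(c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)),
                         sprintf("s%03d", 1:n))
    # sample group 1 dies faster
    time <- stats::rexp(n, ifelse(sgrp == 1, 0.2, 0.02))
  })
  m <- expression_matrix(lg, "LOG2")
  clin <- tibble::tibble(sample_id = colnames(lg), os_time = time,
                         os_event = 1)
  gene_cl <- hclust_cluster(t(scale(t(lg))), k = 2, metric = "euclidean",
                            linkage = "wardD2")$labels
  truth_cl <- rep(c(1, 2), each = 10)
  expect_equal(ari(gene_cl, truth_cl), 1)
  sp <- split_signature_sets(m, gene_cl, setNames(sgrp, colnames(lg)), clin)
  # the block elevated in the short-survival samples becomes set A
  expect_setequal(sp$set_a, sprintf("a%02d", 1:10))
  expect_setequal(sp$set_b, sprintf("b%02d", 1:10))
  expect_equal(sp$poor_group, 1)
  expect_error(
    split_signature_sets(m[1, , drop = FALSE],
                         setNames(1, rownames(m)[1]),
                         setNames(sgrp, colnames(lg)), clin),
    "at least 2 genes")
})

test_that("TMEscore identities hold", {
  m <- random_tpm(60, 10, seed = 76)
  set_x <- rownames(m)[1:8]
  set_y <- rownames(m)[21:30]
  # identical sets cancel exactly
  same <- compute_tmescore(m, set_x, set_x)
  expect_equal(same$tmescore, rep(0, 10))
  # swapping the sets negates every score
  ab <- compute_tmescore(m, set_x, set_y)
  ba <- compute_tmescore(m, set_y, set_x)
  expect_equal(ab$tmescore, -ba$tmescore, tolerance = 1e-12)
  # strictly monotone per-sample transforms leave the score unchanged
  m2 <- expression_matrix(unclass(m)^1.7, "TPM")
  ab2 <- compute_tmescore(m2, set_x, set_y)
  expect_equal(ab2$tmescore, ab$tmescore, tolerance = 1e-12)
})

test_that("the 4-gene worked example gives TMEscore 4", {
  vals <- matrix(c(4, 3, 2, 1), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), "s1"))
  m <- expression_matrix(vals, "TPM")
  sc <- compute_tmescore(m, set_a = "D", set_b = "A")
  expect_equal(sc$tmescore_b, 2)
  expect_equal(sc$tmescore_a, -2)
  expect_equal(sc$tmescore, 4)
})

test_that("maxstat agrees with a brute-force survdiff scan", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 50
      score <- stats::rnorm(n)
      time <- stats::rexp(n, 0.1 * exp(0.8 * score))
      event <- stats::rbinom(n, 1, 0.8)
    })
    if (sum(event) == 0) event[1] <- 1
    got <- maxstat_cutpoint(score, time, event)
    orc <- oracle_maxstat(score, time, event)
    expect_equal(got$cutpoint, orc$cutpoint, tolerance = 1e-12)
    expect_equal(got$max_statistic, orc$max_statistic, tolerance = 1e-8)
  }
})

test_that("maxstat respects admissibility, gaps, and shift equivariance", {
  # clean gap with all early deaths on one side: the cut lands inside the gap
  withr::with_seed(78, {
    score <- c(seq(0, 1, length.out = 10), seq(10, 11, length.out = 10))
    time <- c(stats::rexp(10, 1) + 0.1, stats::rexp(10, 0.01) + 5)
    event <- rep(1, 20)
  })
  ms <- maxstat_cutpoint(score, time, event)
  expect_gt(ms$cutpoint, 1)
  expect_lt(ms$cutpoint, 10)
  # shift equivariance
  ms2 <- maxstat_cutpoint(score + 7, time, event)
  expect_equal(ms2$cutpoint, ms$cutpoint + 7, tolerance = 1e-10)
  # constant scores admit no cutpoint
  expect_error(maxstat_cutpoint(rep(1, 5), 1:5, rep(1, 5), min_prop = 0.4),
               "constant")
  # n = 5 at min_prop = 0.4: only cuts leaving >= 2 samples per side survive
  ms3 <- maxstat_cutpoint(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), rep(1, 5),
                          min_prop = 0.4)
  expect_equal(ms3$n_candidates, 2L)
  n_low <- vapply(ms3$scan$cutpoint, function(c) sum(c(1:5) <= c), numeric(1))
  expect_true(all(n_low >= 2 & (5 - n_low) >= 2))
})

test_that("signature models freeze, serialize, and score new cohorts", {
  co <- generate_cohort(cohort_config(n_samples = 80, n_genes = 300,
                                      n_cell_types = 4,
                                      genes_per_signature = 6,
                                      n_planted_degs = 10, seed = 77))
  set_a <- co$truth$signature_genes[[2]]
  set_b <- co$truth$signature_genes[[1]]
  model <- fit_tme_signature(co$expression, set_a, set_b, co$clinical)
  expect_s3_class(model, "tme_signature")
  expect_equal(model$scores$tmescore,
               model$scores$tmescore_b - model$scores$tmescore_a)
  expect_setequal(model$scores$risk_label[model$scores$tmescore > model$cutpoint],
                  "high")
  path <- withr::local_tempfile(fileext = ".json")
  write_tme_signature(model, path)
  back <- read_tme_signature(path)
  expect_equal(back$set_a, model$set_a)
  expect_equal(back$cutpoint, model$cutpoint)
  sc <- score_cohort(back, co$expression)
  expect_equal(sc$tmescore, model$scores$tmescore)
  expect_equal(sc$risk_label, model$scores$risk_label)
  # low gene coverage aborts
  keep <- setdiff(rownames(co$expression), set_a[-1])
  expect_error(score_cohort(back, co$expression[keep, ]), "coverage")
})
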