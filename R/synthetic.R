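#' Configuration for a synthetic TME cohort
#'
#' Bundles all generating-model parameters with validation. Defaults describe
#' the cohort the package's own evaluations run on: 300 samples, 2000 genes,
#' 12 cell-type signatures of 10 genes, three latent TME groups in equal
#' proportions, a 2 log2-unit infiltration shift, 60 planted DEGs at log2FC
#' 2, exponential survival with log-hazard 1 per unit latent score and ~30%
#' independent uniform censoring, and a logistic response model tied to the
#' same latent score.
#'
#' The latent score of a sample is the planted log2 shift of the first
#' cell-type block minus that of the second block, so its true orientation is
#' known to tests: samples in group 1 score `+infiltration_effect`, group 2
#' `-infiltration_effect`, remaining groups 0. With the default positive
#' `survival_beta` the score acts as an adversity score — the hazard is
#' proportional to `exp(survival_beta * latent)`, so high-scoring samples die
#' sooner — and the default negative `response_slope` aligns immunotherapy
#' response with good prognosis, the configuration the downstream workflow
#' is evaluated against.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_cell_types,genes_per_signature Number and size of planted
#'   cell-type signature blocks.
#' @param n_groups Number of latent TME groups.
#' @param group_proportions Simplex vector of length `n_groups`.
#' @param infiltration_effect log2 shift of a cell type's signature genes in
#'   the group that cell type marks.
#' @param n_planted_degs,deg_log2fc Count and effect size of planted DEGs
#'   (assigned to groups round-robin, elevated in their group).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline log2
#'   abundance distribution.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param survival_beta Log-hazard per unit latent score.
#' @param baseline_hazard Baseline exponential event rate (per month).
#' @param censoring_rate Target fraction censored, in \[0, 1).
#' @param weibull_shape Weibull shape for event times (1 = exponential).
#' @param response_intercept,response_slope Logistic model for the binary
#'   immunotherapy-response label.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300, n_genes = 2000,
                          n_cell_types = 12, genes_per_signature = 10,
                          n_groups = 3,
                          group_proportions = rep(1 / n_groups, n_groups),
                          infiltration_effect = 2,
                          n_planted_degs = 60, deg_log2fc = 2,
                          baseline_log2_mean = 6, baseline_log2_sd = 2,
                          noise_sd = 1,
                          survival_beta = 1, baseline_hazard = 0.02,
                          censoring_rate = 0.3, weibull_shape = 1,
                          response_intercept = -0.5, response_slope = -2,
                          seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_cell_types = as.integer(n_cell_types),
    genes_per_signature = as.integer(genes_per_signature),
    n_groups = as.integer(n_groups),
    group_proportions = as.numeric(group_proportions),
    infiltration_effect = infiltration_effect,
    n_planted_degs = as.integer(n_planted_degs), deg_log2fc = deg_log2fc,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
    survival_beta = survival_beta, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, weibull_shape = weibull_shape,
    response_intercept = response_intercept, response_slope = response_slope,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_samples >= 2L, cfg$n_genes >= 1L,
    cfg$n_cell_types >= 2L, cfg$n_groups >= 2L,
    length(cfg$group_proportions) == cfg$n_groups,
    all(cfg$group_proportions > 0),
    abs(sum(cfg$group_proportions) - 1) < 1e-8,
    cfg$baseline_log2_sd > 0, cfg$noise_sd > 0,
    cfg$baseline_hazard > 0, cfg$weibull_shape > 0,
    cfg$censoring_rate >= 0, cfg$censoring_rate < 1
  )
  n_sig <- cfg$n_cell_types * cfg$genes_per_signature
  if (n_sig + cfg$n_planted_degs > cfg$n_genes) {
    abort(sprintf(
      "gene budget infeasible: %d signature + %d DEG genes exceed n_genes = %d.",
      n_sig, cfg$n_planted_degs, cfg$n_genes
    ))
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort with planted TME structure
#'
#' Builds expression as `2^(baseline + planted shifts + noise)` and rescales
#' each sample to TPM. Cell types are assigned to latent groups round-robin;
#' a cell type's signature genes are shifted up by `infiltration_effect`
#' (log2) in the samples of its group. Planted DEGs are likewise elevated by
#' `deg_log2fc` in their assigned group. Event times follow a Weibull (by
#' default exponential) hazard proportional to `exp(survival_beta *
#' latent_score)`; censoring times are drawn independently from a uniform
#' distribution whose upper bound is solved numerically so the expected
#' censored fraction matches `censoring_rate`. A binary response label is
#' drawn from `plogis(response_intercept + response_slope * latent_score)`.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with elements:
#'   * `expression` — an [expression_matrix()] in TPM;
#'   * `clinical` — tibble `sample_id`, `os_time` (months), `os_event`,
#'     `response`, `group`, `latent_score`;
#'   * `signatures` — named list of cell-type signature gene sets;
#'   * `truth` — list with `group`, `latent_score`, `signature_genes`,
#'     `deg_table` (planted DEG IDs, group, true log2FC), `survival_beta`,
#'     `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config.")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    g <- cfg$n_genes
    gene_ids <- sprintf("gene%04d", seq_len(g))
    sample_ids <- sprintf("sample%03d", seq_len(n))

    group <- sample(rep(seq_len(cfg$n_groups),
                        times = stats::rmultinom(1, n, cfg$group_proportions)[, 1]))

    # gene layout: signature blocks first, then planted DEGs, then background
    sig_idx <- seq_len(cfg$n_cell_types * cfg$genes_per_signature)
    sig_genes <- split(gene_ids[sig_idx],
                       rep(seq_len(cfg$n_cell_types), each = cfg$genes_per_signature))
    names(sig_genes) <- sprintf("celltype%02d", seq_len(cfg$n_cell_types))
    cell_group <- rep(seq_len(cfg$n_groups), length.out = cfg$n_cell_types)

    deg_idx <- seq(max(sig_idx) + 1L, length.out = cfg$n_planted_degs)
    deg_group <- if (cfg$n_planted_degs > 0L) {
      rep(seq_len(cfg$n_groups), length.out = cfg$n_planted_degs)
    } else integer(0)

    shift <- matrix(0, g, n)
    for (ct in seq_len(cfg$n_cell_types)) {
      rows <- sig_idx[((ct - 1L) * cfg$genes_per_signature + 1L):(ct * cfg$genes_per_signature)]
      shift[rows, group == cell_group[ct]] <- cfg$infiltration_effect
    }
    for (d in seq_along(deg_idx)) {
      shift[deg_idx[d], group == deg_group[d]] <- cfg$deg_log2fc
    }

    # latent score: planted shift of cell-type block 1 minus block 2
    block1 <- sig_idx[seq_len(cfg$genes_per_signature)]
    block2 <- sig_idx[cfg$genes_per_signature + seq_len(cfg$genes_per_signature)]
    latent <- colMeans(shift[block1, , drop = FALSE]) -
      colMeans(shift[block2, , drop = FALSE])

    baseline <- stats::rnorm(g, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    log2expr <- baseline + shift +
      matrix(stats::rnorm(g * n, 0, cfg$noise_sd), g, n)
    vals <- 2^log2expr
    dimnames(vals) <- list(gene_ids, sample_ids)
    expr <- fpkm_to_tpm(expression_matrix(vals, unit = "FPKM"))

    rate <- cfg$baseline_hazard * exp(cfg$survival_beta * latent)
    # Weibull with proportional hazards: S(t) = exp(-rate * t^shape)
    u <- stats::runif(n)
    event_time <- (-log(u) / rate)^(1 / cfg$weibull_shape)
    if (cfg$censoring_rate > 0) {
      tau <- solve_censoring_tau(rate, cfg$weibull_shape, cfg$censoring_rate)
      cens_time <- stats::runif(n, 0, tau)
    } else {
      cens_time <- rep(Inf, n)
    }
    os_time <- pmin(event_time, cens_time)
    os_event <- as.integer(event_time <= cens_time)
    os_time <- pmax(os_time, 1e-6)

    p_resp <- stats::plogis(cfg$response_intercept + cfg$response_slope * latent)
    response <- ifelse(stats::runif(n) < p_resp, "responder", "non-responder")

    clinical <- tibble(
      sample_id = sample_ids,
      os_time = os_time,
      os_event = os_event,
      response = response,
      group = group,
      latent_score = latent
    )
    deg_table <- tibble(
      gene_id = gene_ids[deg_idx],
      group = deg_group,
      true_log2fc = rep(cfg$deg_log2fc, cfg$n_planted_degs)
    )
    truth <- list(
      group = setNames(group, sample_ids),
      latent_score = setNames(latent, sample_ids),
      signature_genes = sig_genes,
      cell_type_group = setNames(cell_group, names(sig_genes)),
      deg_table = deg_table,
      survival_beta = cfg$survival_beta,
      config = cfg
    )
    list(expression = expr, clinical = clinical,
         signatures = sig_genes, truth = truth)
  })
}

# uniform-censoring upper bound giving E[censored fraction] = target.
# a sample is censored when C < T; with C ~ U(0, tau) independent of T,
# P(C < T | rate) = E[S(C)] = (1/tau) * integral_0^tau S(t) dt,
# which decreases from 1 to 0 as tau grows
solve_censoring_tau <- function(rate, shape, target) {
  p_cens <- function(tau) {
    mean(vapply(rate, function(r) {
      s <- stats::integrate(function(t) exp(-r * t^shape), 0, tau,
                            rel.tol = 1e-8)$value
      s / tau
    }, numeric(1)))
  }
  lo <- 1e-4
  hi <- 1
  while (p_cens(hi) > target && hi < 1e8) hi <- hi * 4
  stats::uniroot(function(tau) p_cens(tau) - target, c(lo, hi),
                 tol = 1e-6)$root
}

#' Generate a synthetic immunotherapy-response cohort
#'
#' Same generating model as [generate_cohort()]; the response label is
#' guaranteed present, mirroring an anti-PD-1/PD-L1 validation cohort used to
#' test a frozen signature.
#'
#' @param config A [cohort_config()].
#' @return As [generate_cohort()].
#' @export
generate_immunotherapy_cohort <- function(config = cohort_config()) {
  out <- generate_cohort(config)
  stopifnot(!anyNA(out$clinical$response))
  out
}
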