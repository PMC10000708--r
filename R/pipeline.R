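#' Run the full TME scoring workflow
#'
#' Orchestrates the whole analysis on one cohort:
#' 1. ssGSEA of the cell-type signatures, unity-normalized;
#' 2. consensus subtyping of samples on the normalized scores
#'    (complete linkage / Manhattan distance base), k chosen by the
#'    delta-area rule over `k_range`;
#' 3. one-vs-rest moderated-t DEGs between TME groups
#'    (|log2FC| > `lfc_thr`, BH-adjusted p < `deg_alpha`);
#' 4. random-forest contribution filter of the pooled DEGs against the TME
#'    grouping;
#' 5. univariate Cox prognostic filter;
#' 6. consensus clustering of the surviving genes at k = 2
#'    (Ward.D2 / Euclidean base) and a k = 2 sample partition on the same
#'    genes;
#' 7. orientation of gene sets A (adverse) / B (favorable) by the
#'    poorer-prognosis sample group;
#' 8. TMEscore = ssGSEA(B) - ssGSEA(A), maxstat cutpoint, high/low labels;
#' 9. log-rank and Cox evaluation of the dichotomized and continuous score,
#'    per-cell-type enrichment comparison between risk groups, and (when a
#'    `response` column is present) the response-by-risk chi-square.
#'
#' Deterministic given `seed`; each stochastic stage draws from a seed
#' derived from it.
#'
#' @param expression An [expression_matrix()] in TPM (FPKM input is
#'   converted).
#' @param clinical Clinical tibble with `sample_id`, `os_time`, `os_event`,
#'   optionally `response`.
#' @param cell_signatures Named list of cell-type gene sets.
#' @param k_range Candidate sample-subtype counts (default 2:5).
#' @param reps Consensus resampling repetitions (default 100).
#' @param p_item Consensus item-sampling fraction (default 0.8).
#' @param lfc_thr,deg_alpha DEG filter thresholds (defaults 1 and 0.05).
#' @param rf_trees Random-forest size (default 500).
#' @param prognostic_alpha Univariate Cox threshold (default 0.05).
#' @param ssgsea_alpha ssGSEA weight (default 0.25).
#' @param min_prop Maxstat admissibility fraction (default 0.1).
#' @param seed Integer master seed.
#' @return A `tme_pipeline_result` list: `model` (the fitted
#'   `tme_signature`), `subtypes` (per-sample tibble with TME group, gene
#'   group, score, risk label), `k_selection`, `enrichment` (normalized
#'   matrix), `deg` (one-vs-rest result), `gene_counts` (per-stage survivor
#'   counts), `stats` (log-rank, Cox, response tests), `report` (one-row
#'   summary tibble).
#' @export
run_full_pipeline <- function(expression, clinical, cell_signatures,
                              k_range = 2:5, reps = 100, p_item = 0.8,
                              lfc_thr = 1, deg_alpha = 0.05,
                              rf_trees = 500, prognostic_alpha = 0.05,
                              ssgsea_alpha = 0.25, min_prop = 0.1,
                              seed = 1) {
  if (expr_unit(expression) == "FPKM") expression <- fpkm_to_tpm(expression)
  clinical <- validate_clinical_table(clinical)
  keep <- intersect(colnames(expression), clinical$sample_id)
  if (length(keep) < 20L) abort("fewer than 20 samples with clinical data.")
  expression <- expression[, keep]
  clinical <- clinical[match(keep, clinical$sample_id), ]

  # 1. cell-type quantification
  enr <- unity_normalize(ssgsea_matrix(expression, cell_signatures,
                                       alpha = ssgsea_alpha))

  # 2. sample subtyping on normalized scores (items = samples)
  sweep_res <- consensus_sweep(t(unclass(enr)), k_range = k_range,
                               reps = reps, p_item = p_item,
                               base = "hclust_complete_manhattan",
                               seed = derive_seed(seed, 11L))
  ksel <- select_k(sweep_res)
  tme_group <- sweep_res[[paste0("k", ksel$k)]]$labels

  # 3. one-vs-rest DEGs between TME groups
  deg <- one_vs_rest_degs(expression, tme_group, lfc_thr = lfc_thr,
                          alpha = deg_alpha)
  deg_union <- unique(unlist(deg$deg_sets, use.names = FALSE))
  if (length(deg_union) < 4L) abort("fewer than 4 DEGs between TME groups.")

  # 4. random-forest contribution filter
  rf_kept <- rf_importance_filter(expression[deg_union, ], tme_group,
                                  n_trees = rf_trees,
                                  seed = derive_seed(seed, 13L))
  if (length(rf_kept) < 4L) abort("fewer than 4 genes survive the RF filter.")

  # 5. prognostic filter
  prog_kept <- prognostic_filter(expression[rf_kept, ], clinical,
                                 alpha = prognostic_alpha)
  if (length(prog_kept) < 4L) {
    abort("fewer than 4 genes survive the prognostic filter.")
  }

  # 6. gene clustering (k = 2) + sample partition on the signature genes
  sig_expr <- expression[prog_kept, ]
  gene_data <- t(scale(t(unclass(log2_transform(sig_expr)))))
  gene_cons <- consensus_cluster(gene_data, k = 2, reps = reps,
                                 p_item = p_item,
                                 base = "hclust_wardD2_euclidean",
                                 seed = derive_seed(seed, 17L))
  sample_groups <- kmeans_cluster(t(gene_data), k = 2, n_init = 10,
                                  seed = derive_seed(seed, 19L))

  # 7. orientation
  split <- split_signature_sets(sig_expr, gene_cons$labels, sample_groups,
                                clinical)

  # 8. score + cutpoint
  model <- fit_tme_signature(expression, split$set_a, split$set_b, clinical,
                             alpha = ssgsea_alpha, min_prop = min_prop,
                             orientation_note = split$orientation_note)

  # 9. evaluation
  sc <- model$scores
  idx <- match(sc$sample_id, clinical$sample_id)
  lr <- logrank_test(clinical$os_time[idx], clinical$os_event[idx],
                     sc$risk_label)
  cox_cont <- cox_ph_fit(clinical$os_time[idx], clinical$os_event[idx],
                         data.frame(tmescore = sc$tmescore))
  cox_bin <- cox_ph_fit(clinical$os_time[idx], clinical$os_event[idx],
                        data.frame(high = as.integer(sc$risk_label == "high")))
  enr_cmp <- compare_enrichment_by_group(enr, setNames(sc$risk_label,
                                                       sc$sample_id))
  resp <- NULL
  if ("response" %in% colnames(clinical) &&
      !anyNA(clinical$response[idx])) {
    tab <- table(risk = sc$risk_label, response = clinical$response[idx])
    resp <- if (all(dim(tab) == c(2L, 2L))) {
      list(table = tab, test = chi_square_test(tab))
    } else {
      warn("response or risk has a single level; chi-square skipped.")
      list(table = tab, test = NULL)
    }
  }

  subtypes <- tibble(
    sample_id = sc$sample_id,
    tme_group = unname(tme_group[sc$sample_id]),
    gene_group = unname(sample_groups[sc$sample_id]),
    tmescore = sc$tmescore,
    risk_label = sc$risk_label
  )
  gene_counts <- c(deg = length(deg_union), rf = length(rf_kept),
                   prognostic = length(prog_kept))
  report <- tibble(
    n_samples = ncol(expression), n_genes = nrow(expression),
    n_cell_types = nrow(enr), chosen_k = ksel$k,
    n_deg = gene_counts[["deg"]], n_rf = gene_counts[["rf"]],
    n_signature = gene_counts[["prognostic"]],
    n_set_a = length(split$set_a), n_set_b = length(split$set_b),
    cutpoint = model$cutpoint, maxstat_z = model$max_statistic,
    logrank_chi2 = lr$chi2, logrank_p = lr$p_value,
    cox_hr_tmescore = tidy(cox_cont)$hr,
    cox_hr_high = tidy(cox_bin)$hr,
    response_chi2_p = if (!is.null(resp) && !is.null(resp$test))
      resp$test$p_value else NA_real_,
    seed = as.integer(seed)
  )
  structure(
    list(model = model, subtypes = subtypes, k_selection = ksel,
         enrichment = enr, deg = deg, gene_counts = gene_counts,
         stats = list(logrank = lr, cox_tmescore = cox_cont,
                      cox_high_vs_low = cox_bin,
                      enrichment_by_risk = enr_cmp, response = resp),
         report = report),
    class = "tme_pipeline_result"
  )
}

#' @export
print.tme_pipeline_result <- function(x, ...) {
  cat("<tme_pipeline_result>\n")
  print(as.data.frame(x$report))
  invisible(x)
}

#' @export
glance.tme_pipeline_result <- function(x, ...) x$report

#' Validate a frozen signature on an immunotherapy cohort
#'
#' Scores a new cohort with an already-fitted signature (no re-derivation),
#' splits it at the cohort median TMEscore and at the upper quartile, and
#' reports for each split the log-rank survival comparison and the
#' response-by-group chi-square with per-group responder rates.
#'
#' @param model A fitted `tme_signature`.
#' @param expression [expression_matrix()] of the validation cohort.
#' @param clinical Clinical tibble with `response`
#'   (responder/non-responder).
#' @return A list with elements `median_split` and `quartile_split`, each
#'   holding `labels`, `logrank`, `chi_square`, `rates` (tibble of group,
#'   n, responder rate), plus `scores`.
#' @export
validate_on_response_cohort <- function(model, expression, clinical) {
  clinical <- validate_clinical_table(clinical)
  if (!"response" %in% colnames(clinical)) {
    abort("clinical table needs a `response` column.")
  }
  sc <- score_cohort(model, expression)
  idx <- match(sc$sample_id, clinical$sample_id)
  if (anyNA(idx)) abort("clinical table lacks some cohort samples.")
  cl <- clinical[idx, ]

  eval_split <- function(labels) {
    lr <- logrank_test(cl$os_time, cl$os_event, labels)
    tab <- table(group = labels, response = cl$response)
    chi <- if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0) &&
               all(colSums(tab) > 0)) {
      chi_square_test(tab)
    } else {
      warn("degenerate response table; chi-square reported as NA.")
      tibble(chi2 = NA_real_, df = NA_real_, p_value = NA_real_)
    }
    rates <- as_tibble(tab) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        responder_rate = sum(.data$n[.data$response == "responder"]) /
          sum(.data$n),
        n = sum(.data$n),
        .groups = "drop")
    list(labels = labels, logrank = lr, chi_square = chi, rates = rates)
  }

  med <- stats::median(sc$tmescore)
  lab_med <- ifelse(sc$tmescore > med, "high", "low")
  q75 <- stats::quantile(sc$tmescore, 0.75, names = FALSE)
  lab_q <- ifelse(sc$tmescore > q75, "high", "low")
  list(
    scores = sc,
    median_split = eval_split(lab_med),
    quartile_split = eval_split(lab_q)
  )
}
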