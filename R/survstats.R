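#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via [survival::survfit()]. Censorings at an event
#' time are counted at risk for that event (the standard convention).
#'
#' @param time Positive follow-up times.
#' @param event Event indicator, 0 = censored, 1 = event.
#' @param group Optional grouping vector for stratified curves.
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, and `group` when stratified.
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_surv_input(time, event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv)
  } else {
    df <- data.frame(time = time, event = event, group = as.character(group))
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- rep(names(fit$strata), fit$strata)
    out <- tibble(group = sub("^group=", "", strata),
                  time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv)
  }
  class(out) <- c("km_curve", class(out))
  out
}

check_surv_input <- function(time, event) {
  if (!length(time)) abort("empty survival input.")
  if (length(time) != length(event)) abort("`time` and `event` lengths differ.")
  if (any(!is.finite(time)) || any(time <= 0)) abort("`time` must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  invisible(NULL)
}

#' Kaplan-Meier plot
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot step-curve plot.
#' @export
autoplot.km_curve <- function(object, ...) {
  has_group <- "group" %in% colnames(object)
  df <- if (has_group) {
    dplyr::group_modify(dplyr::group_by(object, .data$group), function(d, key) {
      dplyr::bind_rows(tibble(time = 0, survival = 1), d[, c("time", "survival")])
    })
  } else {
    dplyr::bind_rows(tibble(time = 0, survival = 1),
                     object[, c("time", "survival")])
  }
  p <- if (has_group) {
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                     colour = .data$group))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival))
  }
  p + ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square via [survival::survdiff()] (rho = 0):
#' \eqn{\chi^2 = (\sum (O - E))^2 / \sum V} over event times, referred to
#' \eqn{\chi^2_1}.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping vector.
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2L || any(tab == 0)) abort("need two non-empty groups.")
  if (sum(event) < 1L) abort("need at least one event.")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = data.frame(time, event, group))
  df <- length(tab) - 1L
  tibble(chi2 = fit$chisq, df = df,
         p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
         n_groups = length(tab))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with Efron tie handling via
#' [survival::coxph()]; Wald confidence intervals
#' \eqn{\exp(\beta \pm 1.96\,SE)}. Collinear covariates are an error;
#' non-convergence and monotone-likelihood warnings are surfaced in the
#' returned object.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates Numeric vector, matrix, or data frame of covariates
#'   (one row per sample).
#' @return A `cox_fit` object wrapping the `coxph` fit, with [tidy()] and
#'   [glance()] methods.
#' @export
cox_ph_fit <- function(time, event, covariates) {
  check_surv_input(time, event)
  x <- as.matrix(as.data.frame(covariates))
  if (nrow(x) != length(time)) abort("covariate rows must match `time`.")
  if (is.null(colnames(x)) || any(!nzchar(colnames(x)))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (any(apply(x, 2L, stats::sd) == 0)) abort("constant covariate.")
  if (ncol(x) > 1L && qr(scale(x, scale = FALSE))$rank < ncol(x)) {
    abort("collinear covariates.")
  }
  if (sum(event) < ncol(x)) abort("fewer events than covariates.")
  df <- data.frame(.time = time, .event = event, x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 50,
                                                           eps = 1e-9))
  structure(list(fit = fit, n = length(time), n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d\n", x$n, x$n_event))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log hazard), `std_error`, `hr`,
#'   `ci_low`, `ci_high`, `wald_p`.
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    std_error = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    wald_p = co[, "Pr(>|z|)"]
  )
}

#' @export
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n, n_event = x$n_event,
    loglik = x$fit$loglik[length(x$fit$loglik)],
    score_chi2 = unname(s$sctest["test"]),
    score_p = unname(s$sctest["pvalue"]),
    converged = x$fit$iter < 50,
    concordance = unname(s$concordance["C"])
  )
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Exact enumeration for small samples (both groups <= 8, no ties), normal
#' approximation with continuity correction otherwise — the
#' [stats::wilcox.test()] defaults.
#'
#' @param x,y Numeric samples.
#' @param alternative Test sidedness (default two-sided).
#' @return One-row tibble: `u_stat`, `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = TRUE)
  tibble(u_stat = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic on an r x c contingency table without continuity
#' correction, df = (r-1)(c-1).
#'
#' @param tab Matrix/table of non-negative counts with positive margins.
#' @return One-row tibble: `chi2`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must hold non-negative integer counts.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero row/column margin.")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Compare enrichment scores between two sample groups
#'
#' Per gene set: Wilcoxon rank-sum of the scores between the two label
#' groups, BH correction across sets, direction from the sign of the median
#' difference (first level minus second, levels sorted).
#'
#' @param e An `enrichment_matrix`.
#' @param labels Two-level label per sample (matrix column order or named).
#' @return Tibble: `set_name`, `median_diff`, `direction`, `p_value`,
#'   `adj_p`.
#' @export
compare_enrichment_by_group <- function(e, labels) {
  v <- unclass(e)
  if (!is.null(names(labels))) labels <- labels[colnames(v)]
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) abort("`labels` must have exactly two levels.")
  i1 <- labels == lv[1L]
  res <- purrr::map_dfr(rownames(v), function(s) {
    x <- v[s, i1]
    y <- v[s, !i1]
    md <- stats::median(x) - stats::median(y)
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    tibble(set_name = s, median_diff = md,
           direction = ifelse(md >= 0, lv[1L], lv[2L]), p_value = p)
  })
  res$adj_p <- bh_adjust(res$p_value)
  res
}
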