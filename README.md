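# tmescorer

Tumor microenvironment (TME) scoring and subtyping from bulk transcriptomes.

Pancreatic ductal adenocarcinoma — and solid tumors generally — embed the
malignant cells in a microenvironment of immune cells, fibroblasts, and
stroma that shapes prognosis and immunotherapy response. `tmescorer`
implements, as reusable R functions, a complete workflow that turns a
gene-by-sample expression matrix plus survival data into a single
per-sample **TMEscore**:

1. **Infiltration quantification** — single-sample GSEA (ssGSEA) of
   cell-type signature gene sets: per sample, the integral of the
   difference between the rank-weighted in-set CDF
   (weights $r_g^{\alpha}$, $\alpha = 0.25$) and the uniform out-of-set
   CDF, followed by per-cell-type unity normalization to [0, 1].
   ESTIMATE-style stromal/immune scoring with cosine purity is included.
2. **TME subtyping** — Monti consensus clustering (resampling 80% of
   samples, complete linkage / Manhattan distance) of the normalized
   enrichment profiles, with *k* chosen by the consensus-CDF delta-area
   rule guarded by a PAC (proportion of ambiguous clustering) crispness
   check.
3. **Signature derivation** — one-vs-rest empirical-Bayes moderated-t
   differential expression between subtypes (DEG: |log2FC| > 1, BH-adjusted
   p < 0.05), a random-forest permutation-importance filter against the
   subtype labels, and a univariate Cox prognostic screen (Wald p < 0.05).
4. **TMEscore** — surviving genes are consensus-clustered (k = 2) into an
   adverse program (set A, anchored to the poorer-prognosis patient group)
   and a favorable program (set B); then

   `TMEscore = ssGSEA(set B) − ssGSEA(set A)`

   per sample, dichotomized at the maximally selected log-rank cutpoint
   (exhaustive scan, both groups ≥ 10% of samples).
5. **Evaluation** — Kaplan–Meier / log-rank / Cox (Efron ties) on the
   dichotomized and continuous score, per-cell-type Wilcoxon comparisons
   between risk groups, and — for cohorts with an immunotherapy response
   label — responder-rate chi-square tests at median and upper-quartile
   score splits, using the frozen signature without re-derivation.

Because published cohorts (TCGA-PAAD, GEO series, IMvigor210) cannot be
bundled, the package ships a first-class synthetic-cohort generator
(`generate_cohort()`) that plants cell-type infiltration groups, DEGs,
score-dependent exponential survival with independent censoring, and a
logistic response label — every downstream stage is developed and tested
against cohorts whose ground truth is known.

## Worked example

```r
library(tmescorer)

cohort <- generate_cohort(cohort_config(n_samples = 150, n_genes = 1000,
                                        seed = 11))
res <- run_full_pipeline(cohort$expression, cohort$clinical,
                         cohort$signatures, reps = 100, seed = 11)
res$model
#> <tme_signature> |A| = 60, |B| = 60, alpha = 0.25, cutpoint = -226.8733 (|Z| = 11.86)
#>   set A = gene cluster 1 (mean log2 expression 10.33 vs 7.59 in poorer-prognosis sample group 1)
#> risk
#> high  low
#>   94   56
```

The pipeline recovered the three planted TME subtypes
(`glance(res)$chosen_k` is 3), funneled 180 one-vs-rest DEGs through the
random-forest and prognostic filters into a 120-gene signature (60 per
program), and the maxstat split of the resulting TMEscore separates
survival sharply:

```r
res$stats$logrank
#> # A tibble: 1 × 4
#>    chi2    df  p_value n_groups
#>   <dbl> <int>    <dbl>    <int>
#> 1  141.     1 1.83e-32        2

tidy(res$stats$cox_high_vs_low)
#> # A tibble: 1 × 7
#>   term  estimate std_error     hr ci_low ci_high   wald_p
#>   <chr>    <dbl>     <dbl>  <dbl>  <dbl>   <dbl>    <dbl>
#> 1 high     -2.63     0.267 0.0719 0.0426   0.121 6.14e-23
```

A hazard ratio of 0.07 for the high-TMEscore group means high scorers die
at ~7% the rate of low scorers — the planted favorable-infiltration
program, recovered with the correct orientation. Scoring an independent
synthetic immunotherapy cohort with the *frozen* model:

```r
val <- generate_immunotherapy_cohort(cohort_config(n_samples = 151, seed = 99))
v <- validate_on_response_cohort(res$model, val$expression, val$clinical)
v$median_split$rates
#> # A tibble: 2 × 3
#>   group responder_rate     n
#>   <chr>          <dbl> <int>
#> 1 high           0.84     75
#> 2 low            0.145    76

v$median_split$chi_square
#> # A tibble: 1 × 3
#>    chi2    df  p_value
#>   <dbl> <int>    <dbl>
#> 1  73.0     1 1.28e-17
```

High-TMEscore patients respond to (simulated) checkpoint blockade at 84%
versus 14.5% — the planted response–prognosis alignment, detected through
the derived score alone.

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods (consensus heatmap, volcano, KM curves, score
distribution). See `vignette("tmescorer-methods")` for the model,
parameter, and design documentation.

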