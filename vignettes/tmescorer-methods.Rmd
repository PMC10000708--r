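---
title: "Methods: TME quantification, subtyping, and the TMEscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME quantification, subtyping, and the TMEscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmescorer)
```

## Overview

`tmescorer` implements a complete workflow for characterizing the tumor
microenvironment (TME) from bulk expression data and distilling it into a
single prognostic score:

1. quantify TME cell infiltration per sample by single-sample GSEA (ssGSEA)
   over cell-type signature gene sets;
2. discover TME subtypes by consensus clustering of the normalized
   infiltration profiles;
3. derive a TME-associated gene signature: one-vs-rest differential
   expression between subtypes, a random-forest contribution filter, and a
   univariate Cox prognostic screen;
4. split the surviving genes into two co-expression programs (sets A and B),
   oriented so that set A tracks the poorer-prognosis patient group;
5. score each sample as `TMEscore = ssGSEA(set B) − ssGSEA(set A)`,
   dichotomize at a maximally selected log-rank cutpoint, and evaluate the
   split against survival and immunotherapy response.

Every stage is driven by the same synthetic-cohort generator, so the whole
pipeline is testable end to end without any external download.

## The ssGSEA statistic

For one sample, genes are ranked by expression (highest expression receives
rank $N$; ties get the average rank). Walking genes in decreasing-rank
order, the in-set empirical CDF increases by $r_g^\alpha / \sum_{g \in S}
r_g^\alpha$ at members of the gene set $S$ and the out-of-set CDF by
$1/(N-m)$ elsewhere. The score is the *sum over all $N$ positions* of the
difference between the two running CDFs — the integral form used by
single-sample enrichment, not the maximum-deviation form of classic GSEA
(which `preranked_gsea()` provides separately, with a gene-permutation
null). With $\alpha = 0.25$ (the default) the weighting is deliberately
mild; because only within-sample ranks enter, any strictly increasing
transform of a sample's expression leaves all of its scores unchanged, so
FPKM/TPM/log choices do not matter for scoring a single sample.

Deterministic tie-break: genes with exactly equal average ranks are walked
in input (row) order.

Per-cell-type scores are rescaled to a unity distribution — row-wise
$(x - \min)/(\max - \min)$ — before subtyping, so each cell type
contributes on the same [0, 1] scale. A constant row is set to zero with a
warning: it carries no between-sample information.

The ESTIMATE-style purity estimate is
$\cos(c_0 + c_1 \cdot (\text{stromal} + \text{immune}))$, with the
published calibration constants as defaults ($c_0 = 0.6049872018$,
$c_1 = 0.0001467884$). These constants were fitted on TCGA Affymetrix data;
on other platforms (and on synthetic cohorts, whose score scale differs)
the purity is a monotone ordering, not a calibrated fraction, and the
constants are exposed as arguments for that reason.

## Consensus clustering and the choice of k

`consensus_cluster()` is Monti-style resampled clustering: at each of
`reps` repetitions, a fraction `p_item` (default 0.8) of items is drawn
without replacement, the base clusterer is run at fixed `k`, and each item
pair's co-clustering is recorded relative to the number of resamples
containing both. Defaults follow the sample-subtyping configuration used
throughout: 1000 repetitions, complete linkage on Manhattan distances; the
pipeline itself runs 100 repetitions, which we found indistinguishable for
the cohort sizes the package targets (the Monte-Carlo variance of consensus
entries shrinks roughly as 1/reps, and one of the test-suite properties
verifies the stabilization empirically). Gene clustering uses
Ward.D2/Euclidean as its base: the originating description of the gene
step ("K-means with Ward.D and Euclidean distance") mixes a flat and a
hierarchical method, and we resolve it in favor of the hierarchical reading,
with `kmeans_euclidean` available as a configuration choice. `stats::kmeans`
(Hartigan–Wong with `nstart` random restarts) stands behind the k-means
option rather than a k-means++ seeding scheme.

Final labels come from average-linkage hierarchical clustering of
`1 − consensus` cut at `k`. Pairs never co-sampled (vanishingly rare at
`p_item = 0.8`, `reps ≥ 100`) get consensus 0 with a warning.

`select_k()` computes the area $A(k)$ under the empirical CDF of
off-diagonal consensus values and the relative delta-area
$\Delta(k) = (A(k) - A(k-1))/A(k-1)$. The delta-area alone cannot return
"no structure": on i.i.d. noise $A(k)$ keeps growing with $k$ even though
no clustering is stable. We therefore pair it with the proportion of
ambiguous clustering, $\mathrm{PAC}(k)$ — the fraction of consensus entries
strictly between 0.1 and 0.9. The chosen $k$ is the largest one with
$\Delta(k) > 0.1$ *and* $\mathrm{PAC}(k) \le 0.2$; if no $k \ge 3$
qualifies, the rule returns 2. On strongly separated three-group data this
selects 3 (with PAC essentially 0); on structureless data every candidate
fails the PAC condition and the rule falls back to 2. Both thresholds are
arguments.

## Differential expression and the DEG filter

Genes are tested on $\log_2(\mathrm{TPM}+1)$ with a moderated two-group t:
per-gene pooled variance $s_g^2$ on $d = n_A + n_B - 2$ degrees of freedom,
a scaled inverse-chi-square prior $(d_0, s_0^2)$ estimated by matching the
moments of $\log s_g^2$ (closed-form, via trigamma inversion), posterior
variance $\tilde s^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, and a t reference
with $d_0 + d$ degrees of freedom. The implementation is checked in the
test suite against an ordinary pooled-t oracle when the prior is disabled
($d_0 = 0$), against full shrinkage at $d_0 \to \infty$, and against
limma's empirical-Bayes fit on identical inputs.

A DEG requires $|\log_2 \mathrm{FC}| > 1$ (both directions — the subtype
comparisons treat up- and down-regulated genes alike, so the threshold is
two-sided) *and* BH-adjusted $p < 0.05$; both inequalities are strict.
One-vs-rest comparisons across $k$ subtypes reuse the same test with the
rest pooled. Note a structural property of one-vs-rest designs: a gene
elevated in one group necessarily appears negatively shifted in the other
groups' contrasts, so overlap between per-group DEG sets concentrates
entirely in the down-regulated calls; the up-regulated sets are disjoint
for group-specific genes.

No voom-style precision weights and no covariates are used: the
comparisons are plain two-group contrasts. Whether the original analyses
ran on TPM, log-TPM, or array intensities is not stated per dataset; the
$\log_2(\mathrm{TPM}+1)$ choice here is a documented convention, not an
inference.

## Signature derivation and the TMEscore

The pooled one-vs-rest DEGs pass through two screens:

* **Random-forest contribution.** A random forest (500 trees) classifies
  the TME subtype from the candidate genes; genes with out-of-bag
  permutation importance (unscaled mean decrease in accuracy) ≤ 0 are
  dropped. The `top_n` rule is available where a fixed signature size is
  preferred. No importance cutoff is inherited from the source analysis;
  "importance > 0" is the package's documented default.
* **Prognostic screen.** Univariate Cox on each gene's
  $\log_2(\mathrm{TPM}+1)$; keep Wald $p < 0.05$. "Influences the
  prognosis" is realized as this univariate screen — a surrogate, exposed
  via `alpha`.

Surviving genes are consensus-clustered (k = 2, Ward.D2/Euclidean on
row-standardized log expression) into two programs, and samples are
partitioned (k = 2) on the same genes. The gene cluster whose mean
expression is higher in the poorer-prognosis sample group (sign of the Cox
coefficient on the partition indicator) becomes **set A**; the other, **set
B**. `TMEscore = ssGSEA(B) − ssGSEA(A)` therefore increases with the
favorable program by construction, whichever way the generating process was
oriented. Raw (not unity-normalized) component scores are subtracted —
they are two like-scaled quantities from the same sample; a `normalize`
flag exists for the alternative.

## Survival machinery

Kaplan–Meier, log-rank, and Cox fits are delegated to the `survival`
package (Efron tie handling; Wald 95% intervals, matching the HR (CI)
reporting style), with hand-tabulated O/E/V oracles in the test suite. The
maxstat cutpoint is an exhaustive scan: candidate cutpoints are midpoints
between consecutive distinct score values leaving at least
$\lceil 0.1\,n \rceil$ samples on each side; each induces a two-group
standardized log-rank statistic $|Z|$, and the maximizing candidate wins
(ties to the smaller cutpoint). The selection maximizes a statistic, so the
log-rank p-value reported for the selected split is anti-conservative — the
test suite verifies this on null scores — and the cutpoint should be read
as a stratification device, not a hypothesis test; no selection-corrected
p-value is applied, matching common practice in this literature.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with defaults chosen once as the package's study conditions: 300
samples, 2000 genes, 12 cell-type signatures of 10 genes each, three latent
TME groups in equal proportions, a 2 log2-unit infiltration shift of a cell
type's signature genes in the group it marks, 60 planted DEGs at log2FC 2,
gene baselines $\mathcal{N}(6, 2^2)$ on the log2 scale with
$\mathcal{N}(0, 1)$ noise, and column rescaling to TPM.

The latent score of a sample is the planted shift of cell-type block 1
minus block 2 (+2 / −2 / 0 for the three groups), and enters two outcome
models:

* **Survival**: event times are Weibull (exponential by default, for
  closed-form checks) with hazard $h_0 \exp(\beta \cdot \text{latent})$,
  $\beta = 1$, $h_0 = 0.02$ per month (median survival near three years
  for a neutral sample — the aggressive-cancer regime the workflow
  targets). Censoring is independent uniform on $(0, \tau)$ with $\tau$
  solved numerically so the expected censored fraction matches the target
  (default 30%).
* **Response**: Bernoulli with
  $\mathrm{logit}^{-1}(a + b \cdot \text{latent})$, default $a = -0.5$,
  $b = -2$. The negative default slope is deliberate: with $\beta > 0$ the
  latent score is an *adversity* score, and the default response model
  aligns immunotherapy benefit with good prognosis — the configuration the
  downstream validation is evaluated against. Positive or zero slopes
  remain available for null and sensitivity checks.

All randomness flows from one seed through a private RNG scope (the global
random state is untouched); sub-stages of the pipeline draw from seeds
derived deterministically from the master seed.

What the generator does **not** emulate: gene-length and library-size
biases of real TCGA data, batch effects, correlated noise between genes
outside the planted blocks, non-proportional hazards, and platform
differences between discovery and validation cohorts. Passing tests
demonstrate that the machinery recovers planted structure under the stated
model; they do not certify performance on real cohorts with those
additional artifacts.

## Numerical and degenerate-case choices

* Duplicate gene rows on input collapse to the per-sample maximum (the
  common convention when several probes map to one symbol), with a warning.
* Missing expression values are an error by default; per-gene median
  imputation is opt-in. RPKM is treated as FPKM: the TPM rescaling is the
  same formula.
* An all-zero sample is an error in `fpkm_to_tpm` (the rescale is
  undefined), naming the sample.
* Constant covariates and collinear covariate sets are rejected before Cox
  fitting; Newton–Raphson runs to `eps = 1e-9` within 50 iterations and
  non-convergence is surfaced via `glance()$converged`.
* `preranked_gsea` NES divides ES by the mean |null ES| of matching sign;
  its permutation p uses +1 smoothing among matching-sign nulls. When all
  in-set statistics are zero under a positive weight, in-set steps fall
  back to uniform.
* Scoring a new cohort with a frozen signature drops absent genes with a
  reported coverage fraction and aborts below 50% coverage on either set.

## Problem sizes

The packaged evaluations run at the sizes stated above: the end-to-end
checks use 300-sample, 2000-gene cohorts with 100 consensus repetitions,
repeated over 20 seeds; oracle equivalences use 100-gene × 20-sample
fixtures; calibration checks use up to 1000 samples or 200 replicates.
These are the package's standard evaluation sizes; `cohort_config()` scales
all of them.

## Known limitations

* The workflow derives its signature from whatever cohort it is given; it
  does not ship, and does not attempt to reproduce, any published gene
  list.
* The delta-area/PAC rule for `k` is a documented surrogate for a choice
  that is usually made by inspection; on weakly separated data it is
  conservative (returns 2).
* The maxstat split inherits the well-known optimism of maximally selected
  statistics; downstream log-rank/Cox results on the dichotomized score
  should be interpreted accordingly.
* ssGSEA scores scale with the size of the gene universe; scores are
  comparable within a matrix, not across matrices with different gene
  counts.
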