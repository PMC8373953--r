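---
title: "Rank-based immune lncRNA pair signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based immune lncRNA pair signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Most transcriptomic prognostic signatures are linear scores over absolute
expression values, which makes them fragile across platforms and
normalization pipelines. The approach implemented here sidesteps that by
building features from **within-sample rank comparisons**: for an ordered
pair of lncRNAs (A, B), the feature value in a sample is

    (A|B) = 1  if expr(A) > expr(B) in that sample,  else 0.

Any strictly monotone per-sample transformation of the expression values
(log, rank, positive affine scaling, quantile normalization) leaves every
indicator — and therefore everything downstream — unchanged. This scale
invariance is the point of the method and is enforced by a property test.

The full construction is a funnel:

1. **Immune-related lncRNAs** (irlncRNAs): a lncRNA is retained when its
   `log2(x+1)` expression has Pearson `|r| > 0.5` with at least one immune
   gene at `p < 0.001` (t-approximation with `n - 2` df).
2. **Differential expression**: among irlncRNAs, genes with tumor-vs-normal
   `|log2FC| > 2` and BH-adjusted moderated-t `p < 0.05` (limma's
   empirical-Bayes variance shrinkage on `log2(x+1)`; a Welch t-test is
   available as `method = "welch"`).
3. **Pairing**: all `choose(k, 2)` ordered pairs of the k DE irlncRNAs, with
   an occupancy filter keeping pairs whose ones-fraction lies in
   `[0.20, 0.80]` — a pair that is almost always 0 or always 1 carries no
   rank information.
4. **Selection**: univariate Cox (Wald `p < 0.05`), then 10-fold
   cross-validated LASSO-Cox (`glmnet`, partial-likelihood deviance,
   CV-minimum lambda; 100 path values down to 1% of `lambda_max`), then one
   joint unpenalized Cox refit. The refit coefficients define

       Riskscore = sum_i (A|B)_i * beta_i.

5. **Evaluation**: cumulative/dynamic time-dependent ROC at 1/3/5 years
   with Kaplan-Meier weighting, Youden-index cutoff on the 1-year curve,
   high/low stratification (strictly greater than the cutoff), K-M and
   log-rank comparison, univariate/multivariate Cox independence analysis,
   and chi-square / Wilcoxon / Spearman association tests against clinical,
   immune-infiltration and drug-sensitivity tables.

The selection pipeline deliberately reuses the same cohort at every stage
(screen, LASSO, refit, evaluation); no internal train/test split is added.
Reported AUCs are therefore apparent (optimistic) performance, which is the
convention this style of signature analysis follows.

## Time-dependent ROC details

At horizon `t`, cases are subjects with an event by `t` and controls are
subjects surviving past `t`; subjects censored before `t` are neither, and
enter through Kaplan-Meier estimates instead (the cumulative/dynamic
estimator of Heagerty, Lumley and Pepe with KM weighting). For threshold
`c`:

    sens(c) = (1 - S(t | X > c)) * P(X > c) / (1 - S(t))
    spec(c) = 1 - S(t | X > c) * P(X > c) / S(t)

with `S(t | X > c)` the KM estimate within the `X > c` subgroup. Estimates
are clamped to `[0, 1]`; the curve is integrated by trapezoid **in
threshold order** (the estimator's natural parameterization), so the small
non-monotonicities this estimator is known to produce contribute signed,
self-cancelling area rather than spurious zigzags. In the uncensored limit
the curve reduces exactly to the empirical ROC and the AUC equals the
Mann-Whitney statistic, which the test suite asserts to 1e-10. Youden ties
break toward the smallest threshold; a degenerate curve falls back to the
marker median with a warning.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `r_min`, `p_corr` | 0.5, 0.001 | immune-correlation screen thresholds |
| `lfc_min`, `de_alpha` | 2, 0.05 | DE thresholds (log2 scale, BH-adjusted) |
| `occupancy` | [0.20, 0.80] | inclusive ones-fraction band |
| `uni_alpha` | 0.05 | univariate Cox retention |
| `lasso_folds`, `lambda_rule` | 10, `"min"` | CV folds; `"1se"` optional |
| `roc_horizons` | 365/1095/1825 days | 1/3/5 years |
| `min_followup_days` | 30 | strict `<` exclusion; exactly 30 is retained |

Design choices where the underlying method description was ambiguous, made
once and kept:

* **Occupancy band endpoints inclusive.** The 20-80% rule is read as a
  band on the fraction of samples in which the indicator is 1; endpoints
  are included (configurable). The band is symmetric about 0.5, so
  retention does not depend on pair orientation.
* **Ties score 0** under the strict "higher than" rule; under the
  log-normal expression model ties have probability zero.
* **Correlation screen runs on all samples** (tumor + normal) on the
  `log2(x+1)` scale; both are configurable since reasonable analysts
  differ here.
* **Cox ties**: Efron correction (the survival-ecosystem default),
  Breslow by option. Confidence intervals use the fixed multiplier
  `z* = 1.959964` so reported tables are exactly reconstructible from
  `coef` and the CI (`hr = exp(coef)`,
  `se = (log HR.95H - log HR.95L) / (2 z*)`,
  `p = 2(1 - Phi(|coef|/se))`) — see `cox_table_consistency()`.
* **Clinical covariate coding** for the independence analysis: age numeric;
  sex 0/1; stage and T/N/M as ordinal integers; `unknown`-type levels are
  treated as missing and dropped per model, never imputed.
* **Collinear pair indicators** in the multivariate refit are dropped in
  screen order (first kept), with a warning.

## The synthetic cohort generator

`generate_cohort()` produces the statistical structure the analysis
assumes, plus ground truth for recovery tests:

* **Expression** is log-normal: Gaussian on the log2 scale (immune genes
  sd 1.2, lncRNAs sd 1.0, means drawn once per gene), exponentiated to
  FPKM-like positive values.
* **Planted correlation**: each of `n_corr_lncrna` lncRNAs inherits the
  centered log2 profile of a distinct immune gene plus noise with
  sd `1.2 * sqrt(1/rho^2 - 1)`, giving expected Pearson `r = rho_target`
  (default 0.8).
* **Planted DE**: `n_de_lncrna` of the correlated lncRNAs get a tumor-only
  shift of magnitude `de_lfc + U(0, 1)` (default base 2.5) with
  alternating sign.
* **Planted survival signal**: `n_signal_pairs` *disjoint* pairs of DE
  lncRNAs, each pair built with opposite DE direction but equal tumor-side
  mean so its indicator stays near 50% occupancy. Disjoint pairs (rather
  than arbitrary pairs among the DE set) avoid built-in collinearity
  between planted indicators, which keeps the coefficient-recovery
  coverage test well-defined; the feasibility bound is
  `2 * n_signal_pairs <= n_de_lncrna`. Event times are exponential with
  hazard `lambda * exp(true_risk - mean(true_risk))`,
  `true_risk = sum beta_i (A|B)_i`, `|beta| ~ U(0.4, 0.65)` with
  alternating signs.
* **Censoring** is independent exponential with rate
  `lambda * q / (1 - q)` (`censoring_calibration()`), the closed form that
  yields censoring fraction `q` for exponential event times under the null
  linear predictor (default `q = 0.4`).
* **Baseline hazard** defaults to 4.6e-4 per day, i.e. a median survival
  of about 1500 days (~4 years), a realistic figure for a lung
  adenocarcinoma cohort; it keeps all three ROC horizons informative
  (neither saturated with events nor empty of them).
* **Infiltration and score tables**: one CD8-T-cell-like column with
  planted negative association to true risk, one M0-macrophage-like column
  with positive association, pure-noise columns; IPS-CTLA4-like and
  IC50-like columns shifted along true risk in the directions the analysis
  is meant to detect.
* **Determinism**: one master seed; `set.seed()` once at entry, all draws
  sequential, so identical configs give identical cohorts.

What the generator does **not** emulate: batch effects, platform
heterogeneity, library-size artifacts, realistic lncRNA zero-inflation, or
correlation between clinical stage and survival (stage is drawn
independently so that the independence analysis has a known answer:
only the risk score should matter). Passing tests on synthetic cohorts
therefore demonstrate correctness of the machinery and recoverability of
planted structure — not clinical validity on real data.

## Numerical choices and degenerate inputs

* Cox fits run to gradient tolerance 1e-9 (at most 100 iterations);
  non-convergence, monotone likelihood, or aliased (collinear) columns set
  `converged = FALSE` with a warning.
* Zero-variance vectors are skipped in the correlation screen (r is
  undefined); a gene flat in both groups with zero mean difference gets
  `p = 1` in DE.
* Duplicate gene rows collapse by linear-scale mean (deterministic and
  order-independent); duplicate sample ids are an error.
* Wilcoxon tests are exact when both groups have at most 8 tie-free
  observations, otherwise tie-corrected normal without continuity
  correction; an all-equal comparison returns `U = n1 n2 / 2`, `p = 1`.
* BH adjustment is the standard step-up; the suite checks it against the
  recursion written from the definition.

## Problem sizes used in the test suite

The packaged tests run the full pipeline on cohorts of 150-400 tumor
samples with 40-120 lncRNAs; coefficient-recovery coverage uses 100
replicate cohorts of the default size (400 tumors, 8 planted pairs), and
the univariate power study uses 40 replicates with a single planted
`|beta| = 0.6` pair — sizes chosen to give the binomial margins quoted in
each test while keeping the suite fast enough to run routinely.

## Known limitations

* The LASSO fold assignment, and hence the selected pair set, depends on
  the seed; only determinism-given-seed is guaranteed, matching standard
  `cv.glmnet` practice.
* The multivariate refit after selection inherits selection bias
  (coefficients away from zero); this is intrinsic to the
  screen-then-refit design, not corrected here.
* The KM-weighted ROC estimator can produce locally non-monotone
  sensitivity/specificity; the nearest-neighbor smoothed variant is not
  implemented.
* Pairing across biotypes (lncRNA-mRNA) and alternative penalties
  (elastic net, ridge) are out of scope.
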