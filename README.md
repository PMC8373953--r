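# lncpairs

Prognostic survival signatures from **rank-based pairs of immune-related
lncRNAs**.

Expression-based prognostic signatures usually score patients with a
weighted sum of absolute expression values, which makes them sensitive to
platform, batch and normalization choices. `lncpairs` implements an
alternative that needs only *which of two genes is higher* within each
sample: for an ordered lncRNA pair (A, B), the feature is

```
(A|B) = 1  if expr(A) > expr(B) in the sample,  0 otherwise
```

so any strictly monotone per-sample transformation of the data (log,
rank, positive scaling, quantile normalization) leaves the signature
unchanged. The package builds the full analysis around this feature:

1. screen lncRNAs by Pearson correlation with immune genes
   (`|r| > 0.5`, `p < 0.001`, on `log2(x+1)`);
2. keep those differentially expressed between tumor and normal
   (`|log2FC| > 2`, BH-adjusted moderated-t `p < 0.05`);
3. form all pairs and keep the informative ones (ones-fraction in
   `[0.20, 0.80]`);
4. select survival-associated pairs by univariate Cox (`p < 0.05`) then
   cross-validated LASSO-Cox, and refit jointly to get
   `Riskscore = Σᵢ (A|B)ᵢ · βᵢ`;
5. evaluate with 1/3/5-year time-dependent ROC (KM-weighted
   cumulative/dynamic estimator), a Youden-index cutoff, Kaplan–Meier /
   log-rank stratification, Cox independence analysis, and association
   tests against clinical covariates, immune-infiltration scores and
   drug-sensitivity (IC50) tables.

A synthetic-cohort generator (`generate_cohort()`) plants all of the
structure the pipeline looks for — immune-gene correlation, tumor/normal
fold changes, proportional-hazards effects on pair indicators,
risk-correlated infiltration columns — with known ground truth, so every
stage is testable end to end.

## Worked example

```r
library(lncpairs)
manifest <- run_pipeline(pipeline_config(seed = 1))
```

The run logs its filtering funnel:

```
[input] 460 samples, 120 lncRNAs, 40 immune genes
[pearson_screen] 30 irlncRNAs
[differential_expression] 19 DEirlncRNAs
[pair_transform] 171 built, 135 within occupancy band
[univariate_screen] 39 survival-related pairs
[lasso] 21 pairs with nonzero penalized coefficients
[signature] 21 pairs in the model
[roc] t365: AUC=0.705, t1095: AUC=0.752, t1825: AUC=0.802
risk groups at cutoff 1.06426: low=300 high=92
[km_logrank] log-rank p = 7.16e-19
```

Reading this: of 120 lncRNAs, 30 pass the immune-correlation screen and 19
of those are differentially expressed; their 171 pairs reduce to 135 after
the occupancy filter, 39 associate with survival univariately, and the
LASSO + multivariate refit keeps 21 in the model. The fitted risk score
separates survival strongly (log-rank p ≈ 7e-19) and discriminates
1-/3-/5-year outcomes with AUC 0.70–0.80. The signature table mirrors the
usual report layout:

```r
head(manifest$signature[, c("covariate", "beta", "hr", "ci_low", "ci_high", "p")], 2)
#>         covariate   beta    hr ci_low ci_high       p
#> 1 LNC0015|LNC0001 -0.273 0.761  0.505    1.15 0.19246
#> 2 LNC0016|LNC0015  0.595 1.813  1.213    2.71 0.00369
```

and the planted immune structure is recovered with the expected signs:

```r
subset(manifest$immune, significant)[1:2, c("cell_type", "rho", "p")]
#>       cell_type    rho        p
#> 1    CD8_T_cell -0.599 1.73e-39
#> 2 Macrophage_M0  0.567 1.10e-34
```

A thin command-line front end is installed with the package
(`system.file("scripts", "lncpairs-cli", package = "lncpairs")`) with
`simulate` and `run` subcommands over YAML configs.

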