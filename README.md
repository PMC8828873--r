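# sig32

Pathway-derived gene signatures, molecular subtypes, and survival risk
scores for gastric cancer expression cohorts.

## The problem

Somatic-mutation catalogs alone miss the pathway-level structure that
carries prognostic information. `sig32` implements, as a tested and
reusable R pipeline, a biomarker-discovery chain for gastric cancer:

1. **Pathway ranking** from pan-cancer somatic mutations by
   network-regularized non-negative tri-factorization
   `X ≈ U S Vᵀ` — `U` the fixed patients-by-cancer-types indicator, `S ≥ 0`
   the cancer-type-by-pathway association scores, `V ≥ 0` gene-by-pathway
   memberships tethered to a pathway-database prior `V₀` and smoothed over a
   gene-interaction network Laplacian `L`:

   `F(S,V) = ‖X − U S Vᵀ‖² + λ_s‖S‖² + λ_l tr(Vᵀ L V) + λ₀‖V − V₀‖²`

   Permutation refits give empirical p values (Benjamini–Hochberg adjusted
   within cancer type); the union of member genes of the top three
   significant pathways is the gene signature (32 genes at the default
   design).
2. **Molecular subtyping** by consensus clustering over repeated NMF runs
   on signature-gene expression, with cophenetic/CDF/delta-area
   diagnostics, and prognosis-ordered group labels (Group 1 best → Group k
   worst).
3. **Subtype classification** of new samples by an all-pairs linear-SVM
   ensemble with uniform-weight additive coupling of pairwise win
   probabilities.
4. **Risk scoring**: a linear SVM trained on the best- vs worst-prognosis
   groups emits the decision value `r = w·x + b` as a continuous risk
   score, converted to predicted five-year overall survival (Cox model,
   Breslow baseline, delta-method confidence bands, score-quartile
   regions).
5. **Survival/response statistics**: Kaplan–Meier with log-rank,
   multivariable Cox (Efron ties), treatment-adjusted marginal survival
   curves (g-computation), bootstrap lasso-Cox, Pearson chi-square without
   continuity correction, one-way ANOVA.

A synthetic-cohort generator with planted pathways, subtypes, proportional-
hazards survival and treatment response stands in for the protected patient
data, so every stage has parameter-recovery tests that need no download.

## Worked example

```r
library(sig32)

cfg <- pipeline_config(outdir = "run1", seed = 1)
manifest <- run_pipeline(cfg)
manifest
#> Pipeline run (seed 1), 7 stages, 50.7 s
#>   signature size 32, selected k = 4, mean LOOCV AUC 1.000
#>   log-rank p = 2e-16, response chi-square p = 1.13e-19
manifest$results$cox
#> Cox proportional hazards (Efron ties)
#>          term                hr        p
#>  age_group>60 1.01 (0.82, 1.24) 9.22e-01
#>       stageII 0.67 (0.37, 1.23) 1.97e-01
#>      stageIII 0.58 (0.32, 1.04) 6.76e-02
#>       stageIV 1.08 (0.49, 2.37) 8.46e-01
#>  groupGroup 2 1.69 (1.18, 2.41) 4.04e-03
#>  groupGroup 3 2.80 (2.00, 3.92) 2.03e-09
#>  groupGroup 4 3.83 (2.75, 5.33) 1.47e-15
```

Reading the output: the simulated pan-cancer mutation data carry three
pathways planted in the target cancer type; the discovery stage ranks them
first and extracts their 32-gene union as the signature. Consensus NMF on
the 567-sample expression cohort selects k = 4 subtypes (adjusted Rand
index 1.0 against the plant at the default separation), the all-pairs SVM
reproduces the labels at mean leave-one-out AUC 1.0, and the multivariable
Cox fit recovers hazard ratios close to the planted values (1.6, 2.4, 3.4
for Groups 2–4 vs Group 1) while age and stage, which are simulated
independently of survival, stay null. Stage artifacts (ranking CSV,
signature gene list, subtype labels, risk scores, survival curves, fitted
models as JSON) and an md5 manifest land in `outdir`; two runs with the
same seed are hash-for-hash identical.

Individual stages are exposed as ordinary functions with classed results:
`fit_trifactor()`, `rank_pathways()`, `permutation_fdr()`,
`select_signature()`, `log2_quantile_normalize()`, `collapse_probes()`,
`batch_adjust()`, `consensus_cluster()`, `select_k()`, `train_pairwise()`,
`loocv_pairwise()`, `train_risk()`, `risk_score()`, `os5_curve()`,
`km_logrank()`, `cox_fit()`, `adjusted_km()`, `lasso_cox_bootstrap()`,
`chisq_independence()`, `anova_oneway()`.

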