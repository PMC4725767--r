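# proteoSig

Downstream analysis of quantitative tumour proteomics for **cancer subtype
signature discovery**. The package is written for analysts working with
spike-in-normalized (super-SILAC-style) protein expression cohorts: a
proteins × samples matrix of log2(tumour / internal standard) ratios with
substantial, abundance-dependent missingness, and a clinical class label
per sample (e.g. the breast-cancer subtypes ERPR, Her2 and TN).

It provides, as one coherent pipeline or as standalone functions:

* **IO** — generic and protein-groups-export table readers with explicit
  ratio-orientation handling, GMT gene sets, two-level category
  hierarchies, self-describing result tables.
* **Preprocessing** — strict valid-value filtering, downshifted-normal
  imputation of missing-not-at-random values
  (x ~ N(m − 1.8·sd, (0.3·sd)²) per sample), pairwise-complete sample
  correlation with hierarchical clustering.
* **1D annotation enrichment** — for per-protein one-vs-rest mean
  differences Δ, each category is scored by the range-normalized rank
  shift *s* = 2(r̄ᵢₙ − (n+1)/2)/(n − nᵢₙ) ∈ [−1, 1] and tested with the
  two-sided Wilcoxon–Mann–Whitney rank-sum test (exact for n ≤ 12), with
  Benjamini–Hochberg control across categories and independent testing at
  leaf and parent hierarchy levels.
* **Differential expression** — one-vs-rest t-tests, one-way ANOVA, and
  permutation-based FDR: q(protein) = min over thresholds c ≤ its
  statistic of median_π #{t π ≥ c} / #{t obs ≥ c}.
* **Classification** — one-vs-rest linear SVMs (libsvm) with t-test
  feature ranking embedded in random-sampling cross-validation (15% test
  fraction, 250 runs by default); the accuracy-vs-signature-size curve,
  the minimal optimal signature per class with marker directions, ROC/AUC
  (Mann–Whitney, ties ½) and multiclass prediction.
* **Synthetic cohorts** — a generator planting markers, enriched
  categories and logistic MNAR missingness, with the complete
  pre-censoring matrix retained, so every stage is testable against known
  ground truth.

## Worked example

```r
library(proteoSig)

study <- generateSynthetic(syntheticConfig(seed = 42))
x <- study$matrix
x
#> ProteomeSet: 2000 proteins x 40 samples
#>   missing: 20.1% of entries
#>   subtypes: ERPR (14), Her2 (15), TN (11)

nrow(filterMinValid(x, 0.7))            # proteins with >70% valid values
#> [1] 1474

# rank-based category enrichment per class, FDR 5%
enr <- hierarchyEnrichment(x, study$categories, minSize = 5, fdr = 0.05)
head(enr[enr$significant & enr$level == "leaf", ], 3)
#>   class level   category n_in     score      p_value      q_value significant
#> 1  ERPR  leaf SHIFTED_10   30 0.7362142 4.214747e-12 6.692719e-11        TRUE
#> 2  ERPR  leaf SHIFTED_04   30 0.7292323 6.692719e-12 6.692719e-11        TRUE
#> 3  ERPR  leaf SHIFTED_01   30 0.6542620 7.349514e-10 4.899676e-09        TRUE

# impute, then ANOVA with permutation-based FDR
xi <- imputeDownshift(x, seed = 1)
de <- permutationFDR(xi, statistic = "anovaF", nPermutations = 250, seed = 2)
sum(de$significant)
#> [1] 20

# cross-validated one-vs-rest feature selection and the final signature
cv  <- cvFeatureSelection(xi, nRuns = 100, featureGrid = 1:10, seed = 3)
optimalFeatureCounts(cv)
#> ERPR Her2   TN
#>    4    5    3
sig <- extractSignature(xi, optimalFeatureCounts(cv))
sig
#> SubtypeSignature: 12 proteins across 3 classes
#>   ERPR (4): +P00595 -P00724 +P01019 +P01756
#>   Her2 (5): +P01211 +P00054 +P00348 +P00293 -P01468
#>   TN (3): -P01164 +P01435 -P00833

# honest evaluation on a fresh draw from the same population
held <- imputeDownshift(generateFromTruth(study$truth, c(10, 10, 10),
                                          seed = 4), seed = 5)
pred <- predict(sig, held, scores = TRUE)
sc   <- attr(pred, "scores")
rocCurve(sc[, "ERPR"], subtypes(held) == "ERPR", positiveClass = "ERPR")@auc
#> [1] 0.955
mean(pred == subtypes(held))   # multiclass held-out accuracy
#> [1] 1
```

The signature entries read as: `+P00595` is a *positive* marker of ERPR
(higher in ERPR than in the rest), `-P00724` a negative one. The ERPR/
Her2/TN AUCs on the held-out draw here are 0.955 / 1.000 / 1.000.

The whole chain — read/simulate → filter → correlate → enrich →
ANOVA+FDR → classify → signature/ROC, with every table written to disk
plus a manifest that reproduces the run byte-for-byte — is available as
`runPipeline(runConfig(...), outDir)`, or from a shell via
`inst/scripts/run_pipeline.R`.

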