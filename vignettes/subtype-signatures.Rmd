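---
title: "Methods: subtype signatures from quantitative tumour proteomes"
author: "proteoSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype signatures from quantitative tumour proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoSig)
```

# The data model

proteoSig analyses cohorts quantified against a common internal standard
(super-SILAC): each measurement is the ratio of a protein's abundance in a
tumour sample to its abundance in a spike-in standard shared by all samples.
The central object, `ProteomeSet`, is a `SummarizedExperiment` whose
`"logratio"` assay holds these values in **log2 sample/standard
orientation**, with `NA` marking proteins not quantified in a sample.
Missing entries carry no numeric meaning and are excluded from every
statistic unless an operation imputes them explicitly.

Log base 2 is used throughout: fold statements convert cleanly (a
"within fivefold" ratio band is |log2 ratio − baseline| ≤ log2 5 ≈ 2.32),
and inter-subtype effects in tissue cohorts are typically below twofold,
i.e. below 1 on this scale. Ratio tables on disk may be oriented either
way; heavy/light exports conventionally report standard-over-sample, so the
`maxquant` reader dialect inverts signs by default while the generic dialect
does not — both are overridable, because legends of published tables rarely
state the numerator unambiguously. Zeros in ratio columns are treated as
non-detections, not measurements, and become missing before the log.

# Filtering and imputation

`filterMinValid()` keeps proteins whose fraction of valid values *strictly*
exceeds a threshold (default 0.7), either over all samples or within at
least one class. The strict inequality mirrors the usual ">70% of samples"
phrasing: 28/40 samples (exactly 70%) does not pass, 29/40 does.

Values are missing mostly because a protein sits near the detection limit
in that sample — missingness depends on the unobserved value itself (MNAR).
`imputeDownshift()` therefore draws replacements from a Gaussian placed in
the low tail of each sample's observed distribution:

$$x_{\text{imputed}} \sim N\!\left(m_s - d\,\sigma_s,\; (w\,\sigma_s)^2\right)$$

with per-sample observed mean $m_s$ and s.d. $\sigma_s$. The defaults
$d = 1.8$ (downshift) and $w = 0.3$ (width) are the long-standing defaults
of this imputation family in proteomics practice; both are in units of the
per-sample s.d., so they adapt to each sample's spread. Observed entries
are never altered, and a fixed seed reproduces the draw bit for bit.

Imputation is performed **once on the full matrix** before classification,
not inside each cross-validation split. This matches the usual pipeline
order ("impute, then classify") but leaks a small amount of information
across splits: the imputed values of test samples depend only on that
sample's own observed values (imputation is per sample), so the leak is
confined to the survival of the same imputed values across runs, not to
label information. Callers wanting a fully split-clean protocol can impute
training and test sets separately around `cvFeatureSelection()`.

`correlationStructure()` uses pairwise-complete Pearson correlation so it
can run on unimputed data, and clusters samples on the distance $1 - r$
(average linkage by default; complete linkage available). Pairs sharing
fewer than 3 observed proteins get a missing correlation, and the samples
responsible are dropped from the dendrogram with a warning.

# Rank-based annotation enrichment

For a target class, `meanDifference()` computes per protein
$\Delta_p = \bar{x}_{\text{in}} - \bar{x}_{\text{out}}$ over observed
values. `enrichment1D()` then asks, for each category (gene set), whether
its members' $\Delta$ values are shifted against the global distribution.
With all $n$ scored proteins ranked ascending (average ranks on ties) and
$\bar r_{in}$ the members' mean rank, the score is

$$s = \frac{2\,\left(\bar r_{in} - \frac{n+1}{2}\right)}{n - n_{in}} \in [-1, 1],$$

equal to +1 exactly when the members hold the $n_{in}$ top ranks (category
enriched for high expression in that class) and −1 for the bottom ranks.
Significance is the two-sided Wilcoxon–Mann–Whitney test on the member
rank-sum: for $n \le 12$ the null distribution is enumerated exactly over
all $\binom{n}{n_{in}}$ placements (ties included); above that a normal
approximation with tie and continuity correction is used. Benjamini–
Hochberg correction is applied across all tested categories, at FDR 5% by
default; a raw p-value cutoff can be requested instead, since gene-set
screens of this kind have historically also been reported at fixed raw
thresholds.

Proteins without a computable mean difference are dropped from the ranking
rather than assigned midranks — a protein with no data carries no evidence
of central position. Categories with fewer than `minSize` (default 5)
scored members, or spanning every scored protein, are excluded.

`hierarchyEnrichment()` runs this per class at two hierarchy levels
(KEGG-BRITE-style): leaf categories as given, and parent categories formed
as the union of their children's members. A protein shared by several
children of one parent is counted once — double-counting would let a single
protein's rank enter a parent's rank-sum twice. BH correction is applied
independently per class and level. Categories without a parent link are
tested with the leaves but labelled level `"none"`.

# Differential expression and permutation FDR

`ttestOVR()` is the classical pooled-variance two-sample t-test of one
class against the rest, signed so positive means higher in the target
class; `anovaF()` is the one-way fixed-effects ANOVA over all classes with
p-values from $F_{k-1,\,N-k}$. Proteins with fewer than 2 observed values
in a group are reported as `NA` rather than silently dropped. A protein
with no variance at all follows the $F = 0$, $p = 1$ convention. An
optional `s0` fudge constant (SAM-style) stabilizes small-variance
t-statistics; it defaults to 0 and applies only to the t route, as the
method that defines it is formulated for t-statistics.

`permutationFDR()` estimates the false discovery rate nonparametrically:
the statistic vector is recomputed under random class-size-preserving
relabelings, and for a threshold $c$,

$$\widehat{FDR}(c) = \frac{\mathrm{median}_{\pi}\,\#\{t^{\pi} \ge c\}}{\#\{t^{obs} \ge c\}}.$$

A protein's q-value is the smallest $\widehat{FDR}(c)$ over all candidate
thresholds at or below its own statistic (candidates are the observed
statistics), which is automatically non-increasing in the statistic. The
median (rather than mean) of the permutation counts is used for robustness
against occasional extreme relabelings. Counts use $\ge$ on both sides, so
ties are handled consistently. When the cohort admits fewer distinct
relabelings than requested, all distinct ones are used (with a warning).

Two numerical properties of this estimator are worth knowing. First, it is
quantized: $\widehat{FDR}$ moves in steps of roughly
$1/\#\{t^{obs} \ge c\}$, so q-values from independent permutation runs can
differ by a few hundredths at mid-range thresholds even at 1,000
permutations, although the significant set at the 5% level is stable in
our tests. Second, with 250 permutations (the default, matching the
resampling scale used elsewhere in the framework) the smallest resolvable
non-zero FDR at a threshold passed by $m$ proteins is $0.5/m$.

# The classification framework

The signature-discovery framework embeds feature selection in random
sampling cross-validation:

1. Draw a test set of 15% of samples (stratified per class by default —
   with ~40 samples an unstratified draw can easily miss a class; an
   unstratified mode exists for fidelity experiments).
2. On the **training set only**, rank proteins per class by the
   one-vs-rest t-test p-value (ties: larger |t| first, then protein id —
   the ranking is fully deterministic).
3. For each signature size $g$ on the grid, train a linear soft-margin SVM
   (libsvm via e1071) on the top-$g$ features and record its binary
   accuracy on the test set.
4. Repeat (default 250 runs) and average: the accuracy curve.

The optimal size per class is the smallest $g$ attaining the curve's
maximum — the minimum number of proteins that classifies with the smallest
error. The final signature re-ranks on the full data (the training-set
rankings exist to estimate accuracy honestly; the one published list must
come from all samples), takes the top $g_c$ per class with the sign of the
class mean difference as direction, and trains the final one-vs-rest
models on exactly those proteins. A protein may mark two classes; (class,
protein) pairs are unique.

A linear kernel with $C = 1$ and per-feature standardization (training
means/s.d.s stored as part of the model) is used throughout: a ranked list
of individually discriminative proteins is only interpretable with a
linear decision function, and no kernel/hyperparameter search is
performed, deliberately — the cross-validation here estimates accuracy as
a function of signature size, not of model complexity. Features with zero
training variance are dropped with a warning before standardization.

`rocCurve()` sweeps the threshold over distinct decision scores; the AUC
is the Mann–Whitney probability that a positive outscores a negative (ties
half), which equals the trapezoidal area under the curve. ROC reporting on
the training cohort is *resubstitution* (models applied to the data they
were trained on) and labelled as such by the pipeline; honest
out-of-sample scores come from applying the models to fresh samples, as
the acceptance script does with a held-out synthetic draw.

Accuracy in the curve is the per-class binary (one-vs-rest) accuracy of
that class's model; the multiclass accuracy of the combined
largest-score predictor (ties to the earlier class in class order) is
reported separately by `predict()`.

# The synthetic cohort generator

`generateSynthetic()` emulates the statistical structure of a
super-SILAC tumour cohort rather than its biology. Protein $p$ in a sample
of class $c$ measures

$$x = b_p + e_{p,c} + \varepsilon, \qquad
  b_p \sim N(0, \sigma_b^2),\ \varepsilon \sim N(0, \sigma^2),$$

with planted effects $e_{p,c}$: markers receive $\pm$`markerEffect` in
their class (random recorded sign), members of planted enriched categories
receive `categoryShift`. Entries are censored missing with probability
$\mathrm{logistic}(k(\tau - x))$, $\tau$ solved by root-finding so the
expected missing fraction hits the target; low values vanish
preferentially, exactly the regime downshift imputation assumes. At
steepness $k = 0$ the logistic model has no solvable threshold (it returns
½ everywhere), so that setting degenerates, by definition, to uniform
Bernoulli censoring. The complete pre-censoring matrix, all planted
effects, $\tau$ and the configuration are retained in the `SyntheticTruth`
object, so tests can compare observed against true values — impossible
with real data.

Default conditions: 3 classes of 14/15/11 samples (a realistic cohort
split for the three clinical breast-cancer subtypes), 2,000 proteins,
noise s.d. 0.8 (with baseline spread 1.0 this keeps the bulk of values
inside the fivefold band typical of spike-in-normalized ratios), 5 markers
per class at 2.0 log2 units (2.5× noise), 10 enriched categories of 30
proteins shifted by 0.5, an equal number of unshifted decoy categories,
and 20% MNAR missingness at steepness 2. `makeDefaultStudy()` scales the
same scenario to 7,000 proteins with 0.8-unit markers (sub-twofold, as
observed between real tumour subtypes) and 15% missingness.
`generateFromTruth()` draws further samples from a stored population — the
honest held-out cohort for classifier evaluation.

What the generator does **not** emulate: peptide-level quantification and
protein inference, correlated protein modules (beyond the planted
categories), batch structure, heavy-tailed noise, and biological
heterogeneity within a subtype. Passing recovery tests on this generator
therefore demonstrates the statistical machinery is correct, not that real
cohorts will yield signatures of comparable quality.

# Numerical choices and problem sizes

* Exact enrichment null enumeration below $n = 13$; normal approximation
  with continuity and tie correction above. The switch point keeps
  enumeration under ~1,000 subsets.
* Expression values are serialized at 17 significant digits, so
  write/read round-trips are bit-identical and pipeline reruns from a
  manifest are byte-identical (the manifest records no timestamps for the
  same reason).
* Degenerate inputs have stated conventions: all-equal protein
  ($F = 0, p = 1$), zero-variance feature (dropped with warning),
  tied prediction scores (earlier class wins), sample pairs with < 3
  shared proteins (correlation missing, sample dropped from clustering).
* The package's own validation suite runs cross-validation at 40–100 runs
  on 2,000-protein cohorts and 25 generator seeds for recovery medians;
  these sizes were chosen to make the statistical assertions stable while
  keeping the suite fast to run routinely. All module defaults remain at
  the full scale (250 runs, 250 permutations).

# Known limitations

* The permutation-FDR q-values inherit the quantization discussed above;
  interpret small differences between q-values of similar statistics
  accordingly.
* One-shot full-matrix imputation before cross-validation is the default
  protocol; a fully split-clean protocol must be assembled by the caller.
* Parent-level enrichment treats a parent as the deduplicated union of its
  children; alternative roll-ups (e.g. weighting children equally) are not
  offered.
* `selectOptimal`'s earliest-maximum rule is deliberately parsimonious:
  when the accuracy curve saturates, it returns the smallest size at the
  plateau, which may be smaller than the number of truly differential
  proteins. That is the correct answer to "minimum proteins, smallest
  error", but a signature of that size need not contain *all* planted or
  biological markers.
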