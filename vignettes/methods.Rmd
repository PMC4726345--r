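---
title: "Methods: signature discovery and evaluation for recurrent implantation failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery and evaluation for recurrent implantation failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifsignature)
```

## The problem

Recurrent implantation failure (RIF) — repeated failure of good-quality
embryos to implant after IVF/ICSI — may in part reflect a constitutively
non-receptive endometrium. The analysis implemented here asks whether
mid-luteal endometrial expression profiles can distinguish RIF patients from
IVF controls, and whether the strength of a patient's RIF-like expression
pattern stratifies her subsequent implantation chances. The package
re-implements that analysis as a tested pipeline and exercises it end to end
on synthetic data with planted structure, so every stage has a known truth
to recover.

## Data model

The unit of data is a two-channel microarray profile: per probe, the log2
fold change (M value) of a sample against a common reference RNA, plus the
log2 mean spot intensity. Each biological sample is profiled twice in
dye-swap (fluorophores exchanged), giving a forward and a reverse
(reference-over-sample) profile. A sample sheet carries class (RIF/control),
cohort, processing batch (`c1`, `c2b1`, `c2b2`), recruiting center, biopsy
day relative to the urinary LH surge (5–8; day 7 approximates the window of
implantation), and pre-biopsy embryo-transfer and implantation counts.

## Pipeline stages

### Normalization and merging

Intensities are quantile normalized: every column is forced to the
across-column mean of sorted values, preserving within-column ranks. The
implementation resolves ties by first occurrence so the definitional
postcondition — all columns share one value multiset — holds exactly, and it
is idempotent. Dye-swap pairs are merged by averaging the re-oriented fold
changes, `(M_fwd − M_rev)/2`, which cancels dye bias; intensities are
averaged.

### Covariate correction

Biopsy-timing and batch effects are modelled per gene by ordinary
least-squares on level indicators and removed by subtracting each sample's
level coefficient, transforming to a reference level (day 7; batch `c2b1`).
To avoid confounding with class or batch, the timing effect is estimated
only on the cohort-2-batch-1 controls (n = 45) and the batch effect only on
controls (n = 72); these estimation subsets are explicit arguments, never
implicit. Biopsy day is treated as a categorical factor, not a linear slope:
the transformation targets a day-7 reference, which is factor-level
language, and nothing forces the shift between days 5 and 6 to equal that
between 7 and 8. The minor center effect (9 vs 106 samples) is deliberately
not corrected; it cannot be estimated reliably at that size. Correction is
exactly invertible given the model, and `pca_qc()` reports per-component
variance explained plus covariate association (Spearman for ordered
covariates, one-way ANOVA F for categorical) before and after.

### Probe filtering

On the signature discovery samples only: probes with median log2 intensity
at or below 6 are removed (lowly expressed probes are noise-prone), as are
probes whose fold-change SD falls strictly below the median SD of all
probes (invariant probes carry no class information). Both statistics are
computed on the full pre-filter universe. The intensity boundary is
inclusive because the stated rule is "log2 ≤ 6"; the SD boundary keeps ties
at the median, the more conservative reading where no boundary is stated.
SDs use the n−1 denominator.

### Signature discovery

Samples are split 81/34 into discovery and validation sets, stratified so
each part's RIF fraction is within one sample of the overall 43/115. Then,
for 100 rounds: draw 4/5 of the discovery samples without replacement (not
class-stratified — folds missing a class are redrawn and logged); rank all
surviving probes by the absolute signal-to-noise ratio
`(μ_RIF − μ_control)/(σ_RIF + σ_control)`; keep the top 100 probes; train a
linear SVM on them; score the held-out fifth. Ranking ties break by probe id
for determinism. Probes appearing in ≥5 of the 100 top lists form the
signature (the inclusive 5% reading; selection operates at probe level, and
unique genes are derived afterwards through the probe→gene map, unannotated
probes counting as their own gene). The signature is evaluated by
leave-one-out cross-validation on the discovery set (fixed probe set, no
re-selection inside the loop) and by a single classifier trained on all 81
discovery samples and applied once to the 34 validation samples, which a
leakage guard keeps out of every upstream step.

### Classification scores

The classifier is a linear soft-margin SVM (cost 1 — the conventional
default, overridable in `pipeline_config()`; no tuning is performed) on
per-probe standardized features, with training statistics stored in the
model. The signature score is a calibrated probability of RIF obtained by
logistic regression of the class on the SVM decision value, fitted on the
training fold only. This Platt-style calibration is fitted outside libsvm
because libsvm's built-in probability fit draws its own cross-validation
folds from a private random stream, which would break bit-for-bit
reproducibility under the pipeline's seed; a logistic fit on the training
decision values is the same sigmoid family and is deterministic. Scores at
or above 0.5 call RIF (the boundary is inclusive on the RIF side); on
perfectly separable training data the logistic fit saturates and scores
approach 0/1, which is harmless for calling.

### Evaluation

PPV, NPV, sensitivity, specificity and accuracy are reported as percentages
with 95% Wilson score intervals, using the exact normal quantile
(1.959964…) and rounding only at report time. Metrics with zero denominators
are reported as undefined, never 0. The confusion table is tested with the
standard two-sided Fisher exact test (minimum-likelihood convention). ROC
curves and AUC (Mann-Whitney convention, ties at half credit) with DeLong
confidence intervals come from pROC; tests cross-check the AUC against an
independent pairwise-concordance enumeration.

### Gene-set enrichment

Probes are collapsed to genes by averaging M values (gene sets are
gene-level; a best-probe-by-intensity alternative is available). Per gene, a
pooled-variance two-sample t statistic contrasts RIF against control
(Welch is available behind the same switch; pooled is the conventional
single-statistic choice). Per gene set, `Z = (μ_set − μ_all)·√m / σ_all`
over the member genes present, with a two-sided P from the standard normal
and Bonferroni correction over the sets tested. Negative Z means
down-regulated in RIF. Enrichment runs on the entire transcriptome, not the
signature alone. Z is location-invariant and scale-invariant in the gene t
values, and on null data with random sets it is empirically standard normal
(the tests check this by Kolmogorov–Smirnov at 1,000 sets).

### Patient stratification

The per-round discovery procedure — including re-selection of the top
probes each round, since it is the procedure, not a fixed signature, that
is repeated — is rerun over all 115 samples, and each sample's held-out
predictions are tallied into a classification error rate
(misclassifications / predictions; expected predictions ≈ rounds/5). RIF
patients are cut into three groups at 0.1 and 0.9, boundaries inclusive on
the medium side. Controls' error rates are computed and reported but not
grouped. Implantation outcomes are pooled per group over each patient's
pre-biopsy transfers and compared pairwise with the two-sided Fisher test;
treating transfers as independent trials ignores within-patient
correlation, which the output documents. The default uses 1,000 rounds; the
shipped analysis and acceptance runs use 200, at which point per-patient
rates are already stable to ±0.07 (binomial SE at ~40 predictions).

## The synthetic study

`generate_dataset()` emulates the study conditions: 43 RIF / 72 controls
across batches `c1` (22/23), `c2b1` (19/45), `c2b2` (2/4); biopsy days in
proportions 8/27/71/9 over days 5–8; dye-swap pairs with independent
profile noise (SD 0.1); per-gene batch shifts (SD 0.3) and day shifts
(SD 0.2) relative to the `c2b1`/day-7 references; a class effect of
δ = 0.7 log2 units on 100 genes, 81% of them down-regulated in RIF; RIF
subtypes (60% typical at full effect, 20% intermediate at δ/2, 20% null
with control-like expression); per-transfer Bernoulli implantation outcomes
at 62.7% (controls) and 3.2% (RIF-wide mean); and 40 gene sets of which 3
preferentially sample affected genes. Choices the source conditions leave
open, fixed once here:

* **Per-gene noise**: residual SDs are log-normal (median 0.4, log-SD 0.5)
  so the SD-median filter has a real spread to act on; equal SDs would make
  it vacuous.
* **Planted-gene eligibility**: signature genes are planted on probes that
  pass the intensity filter and have above-median baseline variability.
  A signature discovered on filtered data is by construction detectable
  after filtering; planting undetectable "signature" genes would test the
  filter, not the discovery loop.
* **Day allocation**: stratified within class × batch cells (global
  proportions preserved up to rounding) so every day level is estimable on
  the designated 45-control timing subset, as it necessarily was in the
  study whose procedure is being modelled.
* **Subtype implantation rates**: the intermediate subtype implants at 4×
  the typical/null rate, scaled so the RIF-wide expectation stays 3.2%.
  This mirrors the observed better prognosis of the intermediate
  error-rate group and gives the group comparison something to find.
* **Effect size δ = 0.7** is a generator default producing recoverable but
  non-trivial signal (per-probe signal-to-noise ≈ 0.4 after subtype
  dilution, ≈ 3–4× the null ranking noise); it is not an estimate of the
  real biology, where no effect-size scale is reported.

What the generator does **not** emulate: probe-level spatial artifacts,
intensity-dependent (loess-type) dye bias, correlated gene modules beyond
the planted sets, RNA-quality covariates, and within-patient correlation of
transfer outcomes. Passing tests therefore demonstrate that the pipeline
recovers the structure it assumes, under that structure — not that the
biological signature itself is reproduced; the study's real-data headline
numbers (such as the 303-gene signature size or a 100% validation PPV)
require the deposited data and are out of scope here.

## Numerical and degenerate-input choices

* All stochastic stages take explicit seeds derived deterministically from
  one global seed (`child_seed()`), so any stage can be reproduced alone.
* Signal-to-noise for a probe with both class SDs zero is defined as 0 with
  a warning; constant features are dropped from SVM training with a warning.
* An empty signature is returned with a warning and downstream training
  refuses it; a sample never held out in stratification gets an undefined
  (NA) error rate, flagged rather than zeroed.
* Fisher tests on tables with a zero margin return P = 1 with a warning.
* Wilson intervals at 0/n and n/n pin the boundary ends to exactly 0 and 1.
* Reports are written with fixed precision so identical runs are
  byte-identical.

## Known limitations

* **Residual timing structure after correction.** The timing model rests on
  ~3 day-5 and ~11 day-6 control samples, so its coefficients carry
  estimation noise of the same order as the planted shifts
  (σ²(1/3 + 1/28) ≈ 0.06 per gene for day 5 against a planted variance of
  0.04). Subtracting them removes the planted structure (the leading-PC
  day association drops from P ≈ 10⁻¹⁴ to ~10⁻⁴–10⁻²) but injects a
  coherent displacement shared by each level's non-estimation samples, so a
  rank-correlation test on the top components can remain nominally
  significant. This is intrinsic to per-gene OLS correction at these subset
  sizes — with more probes the displacement grows relative to noise — and
  shrinkage-style correction is deliberately out of scope. The batch model
  (72 estimation samples) does not show the effect at default settings.
* **Lenient selection threshold.** At ≥5 of 100 rounds, borderline null
  probes that repeatedly ride the bottom of correlated top-100 lists enter
  the signature: at the default design roughly half the selected probes are
  unplanted. The planted/unplanted selection-frequency distributions are
  nonetheless separated overwhelmingly (Mann-Whitney P < 10⁻⁶), which is
  the property the tests assert.
* **Score calibration** is monotone in the SVM decision value by
  construction, so ROC-based conclusions are unaffected by the calibration
  choice; only the probability scale near 0.5 depends on it.
* The exact-test P values reported for confusion tables follow the standard
  two-sided convention; other conventions (doubling the one-sided P) give
  different numbers on the same table.

## Problem sizes

The shipped analysis scripts and the acceptance run use 2,000 probes, 115
samples, 100 discovery rounds, 10 generator seeds for seed-averaged
recoveries, and 200 stratification rounds — sizes at which every planted
structure is comfortably detectable and the whole workflow reruns in about
a minute on a laptop.
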