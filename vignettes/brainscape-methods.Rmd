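---
title: "Methods: building and annotating a brain expression landscape"
author: "brainscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and annotating a brain expression landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainscape)
```

# The problem

Bulk RNA-seq cohorts of brain tumors and normal brain are produced by
different consortia with different quantification pipelines. Pooling
them gives a *reference landscape*: a fixed low-dimensional embedding of
hundreds of adult gliomas, pediatric tumors and normal brain regions on
which sample-level annotations — molecular subtype, survival, pathway
activity, mutation/fusion/copy-number burden — can be overlaid and
compared across disease entities. brainscape implements that pipeline
end to end, together with a synthetic multi-cohort generator so every
stage can be validated against known ground truth without
access-controlled downloads.

# Harmonization

Cohort matrices arrive as FPKM or TPM. FPKM is converted per sample $j$
by

$$\mathrm{TPM}_{ij} = \frac{\mathrm{FPKM}_{ij}}
 {\sum_{i'} \mathrm{FPKM}_{i'j}} \times 10^6,$$

so every column sums to $10^6$; the conversion is idempotent up to
scale. Cohorts are then restricted to the genes shared by all cohorts
and by a user-supplied protein-coding gene list, merged, and
log-transformed as $\log_2(\mathrm{TPM} + 1)$.

Choices worth recording:

* **Pseudocount.** $\log_2$ of TPM is undefined at zero; the $+1$
  pseudocount keeps zeros at zero and preserves within-sample ranking.
* **Duplicate gene symbols** (multiple rows mapping to one symbol) are
  collapsed by keeping the row with the highest mean — deterministic and
  the common practice for symbol-level matrices.
* **Merged gene order** is lexicographic, so the merged matrix does not
  depend on the order cohorts are supplied in.
* The gene list is a plain text file rather than a fetched annotation,
  keeping runs reproducible offline.

# Batch correction

Cohort (pipeline) effects are removed on the log scale with the ComBat
empirical-Bayes location/scale model: per gene, data are standardized,
additive ($\gamma$) and multiplicative ($\delta$) batch effects are
estimated, shrunk toward parametric batch-level priors fitted by
moments, removed, and the pooled scale and grand mean restored. The
`location_scale_eb` mode is backed by `sva::ComBat` — the estimator the
original analyses used. Around it:

* **`mean_only` mode** performs exact per-gene batch-mean centering with
  no shrinkage. With shrinkage, per-gene batch means would retain small
  residuals; exact centering makes "batch means equal after correction"
  a hard guarantee, which is what a mean-shift-only design calls for.
* **Grand-mean restoration.** After either adjustment each gene is
  re-centered to its original grand mean. EB residuals otherwise shift
  per-gene levels by a small amount, and downstream contrasts are easier
  to reason about when correction never changes a gene's overall level.
* **Zero-variance genes** (overall, or within a batch in EB mode) pass
  through unadjusted instead of being dropped, with a message.
* **Sign of corrected values.** Adjusted $\log_2(\mathrm{TPM}+1)$ values
  can dip slightly below zero near the zero floor. They are kept as-is:
  clamping would silently break grand-mean preservation. Containers with
  unit `LOG2TPM` therefore tolerate small negative entries, while
  FPKM/TPM containers remain strictly nonnegative.
* No biological covariates enter the model; batch labels are an input
  (one label per sample), never hard-coded cohort names.

As a quality-control statistic, `batchSilhouette()` reports the mean
silhouette width of the batch labeling over the top principal
directions: near zero (or negative) means batches are mixed.

# The landscape embedding

UMAP (via `uwot`) embeds samples using all genes as features, with the
published defaults: 15 neighbors, minimum distance 0.1, Euclidean
metric, 2 components. The source analyses reported using the method's
defaults, so those are the package defaults; all are configurable. Runs
are deterministic given (input, parameters, seed): the optimizer runs
single-threaded with the seed set immediately before the call, and the
seed and parameters are stored in the returned object and the CSV
sidecar. The 2-D embedding is the canonical analysis surface — survival
annotation and label transfer read 2-D coordinates — while 3-D is
supported for export and viewing.

Label transfer (`knnLabelImpute()`) assigns each unlabeled sample the
majority label of its $k = 15$ nearest labeled samples (Euclidean, in
the embedding), with ties broken by the single nearest labeled
neighbor — deterministic and local. This mirrors how unclassified
medulloblastoma samples can be assigned a subtype from where they sit
among classified ones.

# Subtype rules

Adult diffuse gliomas are classified by the WHO-CNS5 molecular rule:
IDH-mutant plus 1p/19q-codeleted is oligodendroglioma; IDH-mutant with
intact 1p/19q is IDH-mutant astrocytoma; IDH-wildtype is IDH-wildtype
glioblastoma. TP53/ATRX mutation and chromosome 7 gain / 10 loss
corroborate but never override the rule. Two deliberate choices:

* IDH-wildtype tumors recorded below grade 4 are still grouped with
  glioblastoma (one transcriptional group), but flagged.
* Unknown IDH (or IDH-mutant with unknown 1p/19q) yields
  `UNCLASSIFIED`; primary markers are never imputed.

# Survival annotation

Records are first restricted to primary samples with one sample per
patient (lexicographically smallest sample id kept — deterministic).
Kaplan–Meier curves use the standard product-limit estimator
(`survival::survfit`); the **median** is the smallest event time where
$\hat S(t) \le 0.5$. This is interpreted as the KM median — not a plain
median of observed times — because only the KM median can be undefined,
and an undefined median is an explicit, meaningful outcome here
(the sample stays uncolored).

`nnSurvivalAnnotate()` colors each landscape sample with the KM median
of a local cohort: samples of the same subtype **and** dataset within
Euclidean radius 2 of the sample in the 2-D embedding, the sample itself
excluded (avoiding self-leakage of its own survival time). The cohort
size is 25% of the same-(subtype, dataset) sample count, rounded half
away from zero; samples with fewer than 10 qualifying neighbors, or
whose cohort median is undefined, stay unannotated. The radius is in
embedding units and was a qualitative choice in the original analyses;
all three parameters are configurable.

One design question resolves itself: whether to apply the radius filter
before or after taking the $k$ nearest neighbors. The two orders are
provably identical — the cohort is the $\min(k, \#\text{within radius})$
nearest in-radius points either way (if the in-radius count is at most
$k$, every in-radius point is among the $k$ nearest overall, and
conversely). Both orders are implemented behind a flag and a test
asserts their equivalence.

# Pathway scoring and differential testing

Single-sample scores use the gene-set variation (GSVA) statistic,
implemented in the package:

1. per gene, a Gaussian-kernel estimate of the expression CDF across
   samples (bandwidth = per-gene sd/4) gives an expression-level
   statistic robust to scale;
2. per sample, genes are ranked by that statistic and ranks are
   symmetrized about the middle of the list, so both expression extremes
   carry weight;
3. per set and sample, a weighted Kolmogorov–Smirnov random walk
   (weight exponent $\tau = 1$) over the ranked list yields the score as
   the maximum positive plus maximum negative deviation.

This "max deviation difference" variant is bounded in $[-1, 1]$ by
construction: +1 means the set's genes concentrate among the sample's
most expressed genes, −1 among the least. Sets are filtered to
$5 \le |{\rm set} \cap {\rm genes}| \le 500$ by default. Constant genes
get a constant CDF statistic of 0.5 and carry no signal.

Differential testing between phenotype groups uses a moderated
$t$-statistic: per pathway, the pooled two-group variance $s_g^2$ (df
$d$) is shrunk toward a prior $s_0^2$ with prior df $d_0$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
 t_g = \frac{\bar\Delta_g}{\tilde s_g\sqrt{1/n_a + 1/n_b}},$$

on $d_0 + d$ df. The hyperprior is fitted by matching the first two
moments of $\log s_g^2$ under the scaled-$F$ model (trigamma inversion
for $d_0$); homoscedastic data drive $d_0 \to \infty$, and `d0 = 0`
recovers the ordinary pooled $t$ exactly, which makes the shrinkage
directly testable. P-values are Benjamini–Hochberg adjusted across
pathways per comparison; `consensusPathways()` intersects significant
same-direction calls across comparisons (e.g. pathways up in every
glioma subtype versus normal brain).

# Multi-omic overlays

* **Variant merging** unions caller tables, deduplicating on
  (sample, gene, position, alt) — falling back to
  (sample, gene, variant class) when position/alt are unavailable — and
  records the sorted caller list per variant.
* **Mutation burden** counts deduplicated records per sample;
  **fusion burden** first drops non-high-confidence calls from the
  Arriba-style caller (other callers are not confidence-filtered, since
  the filter is defined for that caller's confidence tiers).
* **Copy-number counts** are genes gained (> 0) and lost (< 0) per
  sample in the GISTIC-thresholded {−2..2} matrix.
* **Fusion frequency** per group is the percent of samples carrying at
  least one fusion with the query gene as either partner
  (partner-agnostic).
* **Gene panels** join expression, mutation, copy number and fusion
  status per sample for one gene, with per-source coverage flags so an
  absent assay is distinguishable from a negative call.

# The synthetic-data generator

`simulateCohort()` draws a full multi-cohort bundle from one seed. The
default configuration emulates a scaled-down version of the study
setting: three adult diffuse-glioma subtype groups (120 IDH-wt
glioblastomas, 80 IDH-mutant astrocytomas, 60 oligodendrogliomas), two
pediatric tumor groups (80 low-grade-glioma-like, 80
medulloblastoma-like), 160 normal brain samples, split between two
cohorts processed by different pipelines (additive log2 shift
$\gamma = 1$, noise scale $\delta = 1.3$ by default).

* **Expression.** Log2-scale values are gene mean (uniform on 2–8) +
  a group up-shift (2 log2 units on a dedicated 5% block of genes per
  group) + cohort $\gamma$ + $\delta \times N(0, 1)$ noise,
  exponentiated to FPKM-like positives. Group blocks are disjoint, so
  groups are separable by construction, as tumor entities are in real
  landscapes.
* **Survival** is exponential with group-specific medians — 1.2 years
  for IDH-wt glioblastoma, 6 for IDH-mutant astrocytoma, 12 for
  oligodendroglioma, clinically typical magnitudes — with independent
  uniform censoring whose upper bound is solved so the expected censored
  fraction matches the configured 30%. Independence of the censoring
  mechanism matters: censoring times coupled to event times would bias
  the KM estimate, and an early version of the generator did exactly
  that.
* **Markers** follow the subtype rule exactly at `marker_noise = 0`
  (plus realistic corroborating-marker frequencies: TP53/ATRX mostly
  mutant in astrocytomas, +7/−10 mostly present in glioblastomas), so
  rule-based classification can be scored against truth.
* **Omics.** Variants are Poisson per sample around group-specific
  rates with subtype-consistent drivers; recurrent fusions follow the
  configured rates (EGFR fusions in 18% of glioblastomas,
  KIAA1549–BRAF in 32% of the pediatric low-grade group) plus sparse
  background calls with a 70/20/10 high/medium/low confidence mix; copy
  number is sparse ±1 noise plus driver-gene gains/losses (EGFR gain and
  PTEN loss in glioblastoma, CIC loss in oligodendroglioma).
* A 5% fraction of tumor patients receives an extra *recurrent* sample,
  so the primary/unique survival filter has something to do.

What the generator does **not** emulate: gene–gene correlation beyond
group block shifts, library-size or GC artifacts, read-level noise,
intra-tumoral heterogeneity, or survival depending on anything but group
membership. Passing tests therefore demonstrate algorithmic
correctness under the stated statistical model — not performance on
real consortium data.

# Numerical choices and problem sizes

* TPM columns are checked to $10^{-6}$ relative; expression round trips
  are exact to double precision (full-precision TSV writing).
* KM medians use the $\hat S(t) \le 0.5 + 10^{-12}$ crossing to absorb
  floating-point equality at exact 0.5 steps.
* The cohort-size rounding is half-away-from-zero (`floor(x + 0.5)`),
  not banker's rounding, so cohort sizes are stable across platforms.
* k-NN ties (equidistant neighbors) follow stable ordering by sample
  order; coordinates are continuous so exact ties are measure-zero in
  practice.
* Test and validation runs use scaled-down problem sizes chosen to keep
  the full suite around a minute: 120–1000 genes, 60–600 samples,
  oracle comparisons on up to ~250-sample landscapes over 20 seeds. The
  batch-correction validation runs at the generator default of 1000
  genes, where each group's 50-gene block gives the separability the
  check is about.

# Known limitations

* The GSVA implementation covers the default variant (Gaussian kernel,
  $\tau = 1$, max-deviation-difference); the Poisson kernel and
  alternative scoring variants are not implemented.
* The moderated-$t$ hyperprior uses the log-scale moment fit; the exact
  profile fit differs slightly at very small pathway counts.
* ComBat's nonparametric prior and reference-batch mode are out of
  scope, as is missing-value handling (inputs must be complete).
* UMAP coordinates are deterministic per seed but not comparable across
  uwot versions; embeddings record their seed and parameters for exact
  regeneration.
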