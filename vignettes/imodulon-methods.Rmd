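---
title: "Methods: robust ICA decomposition of expression compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust ICA decomposition of expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A bacterial expression compendium is a genes-by-samples matrix **X** of
log2(TPM + 1) values, centered on a reference condition. The package
factors it as

**X ≈ M · A**

where the columns of **M** (genes × k) are statistically independent
gene-weight vectors and the rows of **A** (k × samples) are their
activity levels per sample, relative to the reference baseline. The
working assumption is that most regulatory signals are *sparse*: a
component's weight vector has a heavy tail of strongly weighted genes
(its iModulon) on a near-Gaussian background of small weights. ICA is
therefore the right blind-source-separation tool, and the departure of
a weight distribution from normality is the membership signal.

```{r}
library(imodulator)
```

## Quality control and normalization

The preprocessing chain is fixed and stage-tagged, so stages cannot be
applied out of order: gene filters → TPM → log transform → replicate
filter → reference centering.

| parameter | default | unit | role |
|---|---|---|---|
| `min_length_nt` | 100 | nt | genes shorter than this are removed |
| `min_fpm` | 10 | fragments/million | genes never reaching this are removed |
| `min_r2` | 0.9 | — | replicate pairs below this R² are removed |
| `variance_threshold` | 0.99 | — | PCA variance fraction for dimensionality |

Both expression boundaries keep the equal case: a 100 nt gene and a
max-FPM of exactly 10 survive; removal requires being strictly below
the threshold, and the replicate rule removes strictly `R² < 0.9`.

Two rules are deliberately explicit because they are genuinely open
choices:

* **FPM quantifier.** A gene is removed only when its *maximum* FPM
  across all samples is below 10. This is the conservative reading:
  a gene induced in a single condition is exactly the kind of signal an
  iModulon analysis is after, so expressed-anywhere genes are kept. The
  rule used is recorded in the QC report (`fpm_rule`).
* **Replicate removal in groups larger than two.** Pairwise R² (squared
  Pearson correlation over genes on the final expression values) cannot
  name a culprit by itself. The package iteratively removes the sample
  with the lowest mean R² to the rest of its group until every remaining
  pair passes, never removing a group's last sample.

A numerical detail: R² is computed as `Sxy² / (Sxx · Syy)` in a single
division rather than `cor()²`. For exact-rational inputs this evaluates
without intermediate rounding, so a pair constructed at R² = 9/10 sits
exactly on the boundary and is kept, as the strict inequality demands.

Centering subtracts, per gene, the mean over the reference-condition
samples — the mean over replicates being the natural estimator of the
baseline — and is idempotent. Microarray intensities enter as log-scale
values and skip the count-based steps; the replicate filter and
centering still apply.

## Dimensionality

The ICA dimensionality d is the smallest number of principal components
explaining 99% of the variance of the centered matrix, with eigenvalues
taken from its SVD. On compendium-scale data this intentionally
overshoots the number of recoverable regulatory signals; the robustness
filter below is what prunes the excess. (On noisy desk-scale synthetic
data the 99% criterion instead approaches min(genes, samples), because
isotropic noise spreads variance across all directions; validation
scenarios therefore pass the known planted dimensionality explicitly.)

## Robust ICA

FastICA is run `n_runs` times (default 100; 20 in the validation
scenarios, which is enough for supports to saturate at 1.0 on planted
data) with the logcosh contrast, unit-variance whitening via SVD,
tolerance 1e-6, at most 1000 fixed-point iterations — the conventional
settings. Each run's randomness enters only through a seeded random
initial rotation, so every run is reproducible, and run seeds are
`base_seed + run index`. Because the input is already reference-centered,
no further per-sample centering is applied inside ICA: the recovered
sources then span exactly the column space of **X**, which is what makes
a noiseless reconstruction exact.

Components pooled across runs are clustered with DBSCAN on the distance
`1 − |ρ|` (absolute Pearson correlation over genes — sign- and
scale-invariant, which Euclidean distance is not), with `eps = 0.1` and
`min_samples = ceiling(n_runs / 2)`. A cluster is retained only when
*strictly more than half* of the distinct runs contribute to it; a run
contributing two near-duplicates counts once. The consensus column is
the sign-aligned mean of the cluster (medoid available), re-normalized
to unit L2. Sign is fixed by the skew-positive convention — flip so the
sum of cubed weights is positive — putting the heavy tail on the
positive side; ties fall back to the largest-|weight| gene.

Activities are the least-squares solution of **X = M·A** via the normal
equations, falling back to the Moore–Penrose pseudoinverse with a
warning if **M** is rank-deficient.

## Membership by the K² statistic

The D'Agostino K² omnibus statistic (transformed skewness plus
transformed kurtosis, ~χ² with 2 df under normality; implemented from
the published moment formulas and cross-checked against an independent
implementation at 1e-10) measures how non-Gaussian a weight vector is.
Genes are removed from the top of the |weight| order — one per
iteration, ties broken by gene order — recomputing K² on the remainder,
until K² drops below the cutoff. Removed genes are the members; the
threshold is the smallest member |weight|, and the member set is closed
over ties so it equals `{g : |w_g| ≥ threshold}` exactly. Components
whose initial K² is already below the cutoff are flagged memberless but
retained, keeping component indices aligned with **A**. K² is computed
on both tails jointly, matching the definition of membership as "large
positive or negative weights". The statistic needs at least 20
observations, so thresholding requires ≥ 20 genes.

The cutoff is organism-specific and has no universal value; the package
default is 550 (a magnitude appropriate for genome-scale weight vectors
of several thousand genes) and `calibrate_cutoff()` sweeps candidates
and reports member-count curves so a dataset-specific choice can be made
and logged. The desk-scale validation fixtures (300–1000 genes) use
cutoff 50: far above the χ²(2) null so pure-noise components stay
memberless, yet small enough that a planted tail of 15–20 genes is fully
stripped before the statistic normalizes.

The removal trace typically decreases, but not strictly: with planted
weights on both tails, removing one side first can transiently raise the
skewness term. The guaranteed invariants — the trace stays at or above
the cutoff until the final step, and the member set is
threshold-consistent — are what the tests assert.

## Explained variance

Reconstruction quality uses only member genes: zero every non-member
weight in **M**, then
`EV = 1 − ‖X − M̃·A‖²_F / ‖X‖²_F`. Per-iModulon values use the analogous
single-component reconstruction against **X**. EV is 1.0 exactly when
the data are noiseless and every nonzero weight is a member, 0.0 when
every component is memberless, and equals the generator's analytic
signal fraction ‖M·A‖² / (‖M·A‖² + σ²·cells) on noisy synthetic data.

## TRN enrichment

Candidate regulator expressions are all single regulators plus all
pairwise unions ("R1/R2") and intersections ("R1+R2"); mixing the two
operators in one expression is not generated and is rejected by the
parser (arbitrary-length homogeneous expressions are accepted for
curated input). Each candidate regulon, clipped to the analysis universe
(the genes retained after QC, not the full genome), is scored by Venn
counts, precision, recall, and the exact hypergeometric upper-tail
p-value. P-values are Benjamini–Hochberg corrected across the candidates
of one iModulon; candidates need q < 0.01 (configurable) and a nonempty
overlap, and the winner maximizes F1 = 2PR/(P+R), with ties preferring
fewer regulators, then lexicographic order. The hypergeometric/BH/F1
combination is a package convention — the selection rule, not the
published curation, which was manual. iModulons sharing a winning
expression get `-1`, `-2`, … suffixes ordered by descending precision.

## Activities and regulator concordance

Condition-level activity is the mean over the condition's samples
(samples are individual observations, conditions the bars of the
dashboard graph), with conditions grouped by project. Regulator
concordance is fit over samples, not condition means, by two models:
an ordinary least-squares line, and a hinge
`y = b` for `x < x0`, `y = b + s(x − x0)` for `x ≥ x0`, whose breakpoint
is chosen by grid search over observed expression values. The grid
excludes the two extreme values on each side so both segments stay
populated, but includes the minimum as a degenerate candidate where the
hinge coincides with the line — making the broken family nest the line,
so `r2_broken ≥ r2_line` holds by construction. Because of that nesting,
raw R² cannot choose the model; the broken line is selected only when it
improves R² by more than 0.1 (configurable). Degenerate inputs (constant
x or y) report R² = 0 and a line.

## The synthetic generator

`planted_scenario()` emulates the statistical structure the model
assumes: a sparse **M** (disjoint supports, 15 genes per module at unit
weight on an optionally non-zero Gaussian background), condition-block
activities (one N(0, 1) activity vector per condition shared by its
replicates; the first condition is the zero-activity reference),
i.i.d. Gaussian measurement noise (σ = 0.25) plus smaller per-replicate
noise (σ = 0.05), in a 300-gene × 40-sample default. Counts mode inverts
the log transform and Poisson-samples a 5-million-read library with
per-gene lengths, exercising the count-based QC path. The defaults give
member genes a signal-to-noise ratio around 4:1 in standard deviation —
comfortable but not trivial, typical of a well-powered compendium.

What it does **not** emulate: correlated noise between co-transcribed
genes, batch and platform effects, overlapping module supports,
regulator-expression feedback, or compositional distortions of TPM.
Passing the planted-recovery tests therefore demonstrates correctness of
the algorithms under the model's own assumptions, not performance on
real compendia, where dimensionality, cutoff and eps need
dataset-specific care.

Validation problem sizes are chosen to exercise every code path at desk
scale: 300×40 with 5 modules and 20 ICA restarts for recovery and
explained variance, 1000-gene weight vectors for membership, 10-run
ensembles for the retention boundary, and a 5-regulator toy TRN for the
exhaustive enrichment oracle.

## Known limitations

* One organism, one compendium per run; no multi-dataset alignment.
* The enrichment search is exhaustive only up to two regulators;
  higher-order boolean combinations must be supplied as curated
  expressions.
* Regulatory effect signs (activation vs repression) are parsed but
  ignored; precision/recall are sign-blind.
* The K² cutoff is a free parameter by design; the package ships a
  calibration sweep, not an auto-chooser.
* No batch correction: compendia assembled across platforms should be
  harmonized before entering the pipeline.
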