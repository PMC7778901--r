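# imodulator

Bacterial transcriptomes are organized by a transcriptional regulatory
network (TRN): regulators switch coherent groups of genes on and off
together. Given a large expression compendium, independent component
analysis (ICA) can recover this structure directly from the data,
factoring the genes-by-samples matrix **X** into statistically
independent gene-weight vectors (**M**) and condition-dependent activity
levels (**A**), with **X ≈ M·A**. The heavy tail of each weight vector
defines an *iModulon* — an independently modulated gene set, the
data-driven counterpart of a regulon.

`imodulator` implements the complete computational pipeline behind such
decompositions, for microbial systems biologists who want to build or
audit them:

- **Quality control and normalization** — removal of genes shorter than
  100 nt or never reaching 10 fragments per million mapped reads (FPM),
  TPM conversion, log2(TPM + 1), removal of biological replicates with
  R² < 0.9, and centering on a reference condition so activities are
  relative to a known baseline. Microarray intensities skip the
  count-based steps.
- **Dimensionality estimation** — the number of principal components
  explaining 99% of the variance, via SVD.
- **Robust ICA** — FastICA (logcosh contrast) restarted from many random
  seeds; components pooled across runs are clustered with DBSCAN on the
  1 − |ρ| distance, and only components recurring in **more than 50% of
  runs** are kept. Consensus columns are sign-aligned means, unit-L2
  normalized. Activities solve **X ≈ M·A** by least squares.
- **Membership thresholding** — per component, genes are stripped from
  the top of the |weight| distribution until the D'Agostino K² normality
  statistic of the remainder falls below an organism-specific cutoff; the
  removed genes are the iModulon.
- **TRN enrichment** — every iModulon is matched against literature
  regulons, including boolean combinations ("R1/R2" = union, "R1+R2" =
  intersection), scored by precision (fraction of iModulon genes in the
  regulon), recall (fraction of regulon genes in the iModulon), and a
  BH-corrected hypergeometric test.
- **Activity summaries** — per-condition mean activities, and
  regulator-expression concordance fit by a line or a broken line (a
  hinge capturing regulators that need a minimum expression level before
  the correlation appears).
- **Synthetic compendia** — a planted-module generator with full ground
  truth (sparse **M**, condition-block **A**, Gaussian noise, replicate
  structure, optional count-level output), so every stage is testable
  end to end without downloading data.

## Worked example

Decompose a synthetic compendium with five planted modules (300 genes,
40 samples = 20 conditions × 2 replicates, noise σ = 0.25):

```r
library(imodulator)

gen <- generate_compendium(planted_scenario(seed = 1))
gen$compendium
#> <compendium> 300 genes x 40 samples, stage = centered

dec <- robust_ica(gen$compendium, d = 5, n_runs = 20, base_seed = 1)
dec
#> <decomposition> 300 genes x 5 components (from 20 runs)

ims <- extract_imodulons(dec, cutoff = 50)
ann <- annotate_imodulons(ims, generate_toy_trn(gen$truth),
                          rownames(gen$compendium))
ann$table
#>   name regulator func category  N precision recall
#> 1 Reg5      Reg5               15         1      1
#> 2 Reg4      Reg4               15         1      1
#> 3 Reg2      Reg2               15         1      1
#> 4 Reg1      Reg1               15         1      1
#> 5 Reg3      Reg3               15         1      1

round(explained_variance(gen$compendium, dec, ims)$overall, 3)
#> [1] 0.747
```

All five planted modules are recovered: each iModulon contains exactly
the 15 planted member genes (N), maps to its planted regulator with
precision and recall 1, and the member-gene reconstruction explains 74.7%
of the variance — the remainder is the injected measurement noise.
`summary_table()` aggregates such per-dataset statistics (genes, samples,
conditions, dimensionality, iModulon counts and percentages, explained
variance) across datasets into a Total column, recomputing percentages
from summed counts.

A thin command-line wrapper with per-stage subcommands (`synth`,
`preprocess`, `decompose`, `threshold`, `enrich`, `activities`, `run`,
`summarize`) is installed at `inst/cli/imodulator.R`.

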