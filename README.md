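# methdisc

Differential methylation and methylation–expression integration for
Infinium 450K-style beta-value matrices in a tumor-versus-normal design —
the setting of global methylation studies of adrenocortical carcinoma
(ACC) against normal adrenal tissue.

The package implements, as tested R functions plus a scripted analysis:

- **Preprocessing**: detection-p, sex-chromosome and SNP-proximity probe
  filters; Infinium I/II probe-type scaling (within-sample quantile
  mapping of type II onto type I); across-sample quantile normalization;
  logit transform to M-values, `M = log2(β/(1−β))` with an ε-clamp.
- **Differential methylation**: per-probe two-sided Wilcoxon rank-sum on
  M-values (exact null for small tie-free groups), Benjamini–Hochberg
  FDR, and calling of differentially methylated loci (DML) at adjusted
  `p < 0.05` and `|Δβ| ≥ 0.2`, where `Δβ = mean(tumor β) − mean(normal β)`.
- **Genomic context**: DML frequency per chromosome normalized to
  chromosome length, distributions over functional position (TSS1500,
  TSS200, 5'UTR, 1stExon, Body, 3'UTR, intergenic) and CpG-island context
  (Island / Shore / Shelf / OpenSea), and complete-linkage Euclidean
  clustering of samples on DML betas.
- **The discretization method** — the core: for each probe, every tumor
  sample is labelled hypermethylated (**M**) or hypomethylated (**U**) by
  the sign of its delta-beta against the normal-mean reference μ (binary;
  a ternary mode adds a neutral band). For every gene-matched
  (methylation probe, expression probe) pair, Welch's unequal-variance
  t-test compares expression between the M and U groups (groups with < 2
  samples excluded), with one BH family across all tested pairs;
  significant pairs are negative correlations when the hypermethylated
  group expresses less.
- **A synthetic-data generator** with planted truth (DML with calibrated
  beta-scale effect sizes; methylation–expression couplings acting
  through each sample's true M/U state), so every stage is testable
  end-to-end without downloads.

See `vignettes/methylation-discretization.Rmd` for the model, parameter
rationale, numerical choices, and known limitations.

## Worked example

The numbered scripts under `analysis/` run a full simulated study — the
target design of 18 tumors vs 6 normals, expression for 14 tumors, 20,000
probes, 200 planted DML (|Δβ| = 0.3) and 100 planted couplings (1.5 log2
units) among 5,000 null pairs:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential_methylation.R
Rscript analysis/04_genomic_context.R
Rscript analysis/05_discretize_correlate.R
```

Output of stages 3 and 5 (seed 1):

```
Tested 19517 probes (18 tumor vs 6 normal): 187 DML called (adj p < 0.05, |delta-beta| >= 0.2): 76 hyper, 111 hypo.
Against planted truth (200 loci): sensitivity 0.935, false-discovery proportion 0.000.
Median beta over DML: tumor 0.500 vs normal 0.674.

Discretization (binary) over 19517 probes x 18 tumors; 5100 gene-matched pairs, 4846 tested (254 skipped for group size < 2).
Significant correlations (BH adj p < 0.05): 55 loci (35 negative, 20 positive); mean group sizes M 6.9 / U 7.0.
Planted couplings recovered: 47 of 100 (47%); direction inversions among recovered: 0.
```

Reading: of the 200 planted DML, 93.5% are recalled with zero false
discoveries, and tumors/normals separate perfectly under complete-linkage
clustering (adjusted Rand index 1.0 in stage 4). The discretization stage
recovers about half of the planted couplings — the analytic power ceiling
at this shift/noise/design (see the vignette) — and never inverts the
direction of a recovered coupling. All tables land under `results/`.

The same pipeline is available as one call with a JSON run manifest:

```r
library(methdisc)
man <- run_all(run_config("results/run1", seed = 1))
man$stages
```

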