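---
title: "Differential methylation and the discretization method: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation and the discretization method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdisc)
```

# The analysis this package implements

`methdisc` implements a two-part analysis of Infinium 450K-style DNA
methylation data in a tumor-versus-normal design, of the kind used to study
adrenocortical carcinoma against normal adrenal tissue (18 tumors vs 6
normals, with expression available for 14 of the tumors):

1. **Differential methylation.** Beta values ($\beta \in [0,1]$, the
   methylated fraction of signal at a CpG probe) are filtered, balanced
   across the two Infinium probe chemistries, quantile-normalized, and
   logit-transformed to M-values, $M = \log_2(\beta/(1-\beta))$.
   A per-probe two-sided Wilcoxon rank-sum test on M-values compares
   tumors to normals; Benjamini–Hochberg correction is applied across all
   surviving probes; a probe is a differentially methylated locus (DML)
   when its adjusted $p < 0.05$ **and** the group-mean difference
   $\Delta\beta = \bar\beta_{tumor} - \bar\beta_{normal}$ satisfies
   $|\Delta\beta| \ge 0.2$.

2. **The discretization method.** For each probe, every tumor sample is
   assigned to a hypermethylated (M) or hypomethylated (U) group by the
   sign of its per-sample delta-beta against the normal-mean reference
   $\mu$ (binary mode), or with a neutral band of half-width $t$ (ternary
   mode). For every (methylation probe, expression probe) pair sharing a
   gene symbol, Welch's unequal-variance $t$-test compares expression
   between the M and U groups; pairs with fewer than 2 samples in either
   group are excluded; BH correction is applied once across all tested
   pairs; a pair with adjusted $p < 0.05$ is a methylation–expression
   correlation, negative when the hypermethylated group expresses less.

This non-linear approach can detect couplings a linear (Pearson/Spearman)
correlation would dilute, because it conditions on each sample's
methylation *state* rather than its methylation *level*.

# Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `p_threshold`, `sample_fraction` | 0.05, 0.25 | a probe is dropped when detection $p >$ 0.05 in $\ge$ 25% of samples; the boundary case (exactly 25%) is removed — the conservative reading |
| `snp_bp` | 10 bp | probes within 10 bp of a catalogued SNP are dropped (inclusive boundary) |
| `epsilon` | $10^{-3}$ | logit clamp; keeps M-values in roughly $[-10, 10]$ and finite at $\beta \in \{0, 1\}$ |
| `alpha`, `min_delta` | 0.05, 0.2 | DML thresholds: strict on adjusted $p$, inclusive on $|\Delta\beta|$ |
| `exact_max` | 49 | largest group size for the exact Wilcoxon null (see below) |
| `ternary_threshold` | 0.1 | neutral-band half width on the beta scale; exposed as a parameter because the original ternary rule is a family, not a single constant |
| `min_group` | 2 | smallest usable discretization group; Welch variance is undefined below 2 |
| `scale` | $10^8$ | chromosome-frequency normalization, count/bp $\times$ scale; raw counts are always emitted alongside, since any such constant is a display choice |

# Numerical and procedural choices

**Wilcoxon branch rule.** The exact null distribution is used whenever both
groups have at most `exact_max = 49` non-missing, tie-free values, the
convention of the R test this pipeline's statistics follow. This matters: at
18 vs 6 the *approximate* (normal, continuity-corrected) p-value at complete
separation is $3.6 \times 10^{-4}$, while the exact floor is
$2/\binom{24}{6} \approx 1.5 \times 10^{-5}$. BH correction across ~20,000
probes cannot push a floor of $3.6\times10^{-4}$ below 0.05 unless thousands
of probes sit on it, so the approximate branch would make small designs
structurally incapable of calling any DML. With ties present, or groups
larger than `exact_max`, the midrank approximation with tie-corrected
variance is used.

**Split statistic scales.** The rank test runs on M-values (approximately
Gaussian, homoscedastic), while $\Delta\beta$ and all discretization
comparisons stay on the beta scale, where the 0.2 threshold has its
biological meaning. $\Delta\beta$ is computed on the post-normalization
betas — the matrices actually analyzed — with a switch for raw betas.

**Probe-type scaling.** Infinium II probes have a compressed dynamic range
relative to type I. Within each sample, type-II values are quantile-mapped
onto the empirical distribution of that sample's type-I values via linear
interpolation between order statistics, on a grid chosen so that identical
distributions map to the identity. The map is monotone (type-II ranks are
preserved) and stays inside $[0,1]$.

**Quantile normalization** delegates to the standard limma implementation
(sorted-value means across samples; missing values interpolated onto the
common grid), which is idempotent and rank-preserving.

**Welch's test** is computed in closed form with Satterthwaite degrees of
freedom rather than through `t.test`, because genome-scale runs hit
degenerate groups that must be defined, not fatal: zero variance in both
groups with equal means gives $t = 0, p = 1$; zero variance with unequal
means gives $p = 0$ with a warning. The implementation is cross-checked
against `t.test` on non-degenerate inputs in the test suite.

**Ties and exclusions.** A tumor sample with $\beta = \mu$ exactly carries
no direction and is excluded from both groups in binary mode (measure-zero
in continuous data, common in toy fixtures). Probes absent from the normal
reference, or with missing beta, are likewise excluded per sample. BH for
the correlation stage uses a single family across all tested pairs — the
most conservative coherent scoping; per-probe families are possible but
would not control the genome-wide FDR.

**Missing values** (`NA`, the TCGA level-3 convention) are excluded
pairwise from every statistic, never imputed as 0; clustering, which needs
a complete matrix, imputes per-probe medians and says so.

# What the synthetic generator emulates

`generate_dataset()` produces the full input bundle with planted truth:

- **Beta values** are logit-normal: a per-probe baseline from a bimodal
  mixture (low mode near $\beta = 0.1$, high mode near 0.85, as array data
  exhibit), plus Gaussian noise (SD 0.5) on the logit scale, mapped back
  through the logistic — so betas are strictly inside $(0,1)$ and the
  pipeline's logit transform exactly Gaussianizes them. This is the
  best-case regime for the method; it makes recovery tests a test of the
  implementation, not of the model's robustness.
- **Planted DML** shift tumor logit means by a per-probe amount solved
  numerically (quadrature + root finding, `calibrate_shift()`) so the
  *expected* beta-scale $\Delta\beta$ equals the 0.3 target to $10^{-3}$.
  The *empirical* group difference still carries sampling noise of
  SE $\approx$ 0.06, dominated by the 6-normal mean.
- **Planted couplings** act through the sample's true M/U state: coupled
  expression probes are shifted by $\pm$1.5 log2 units in tumors whose
  planted methylation state is M, so discretization is the correctly
  specified estimator.
- **Infinium II compression** is emulated by shrinking type-II betas
  toward 0.5 by a factor 0.9; probe-type scaling in preprocessing undoes
  it. Sporadic detection failures (0.2% of cells), 20 wholly-failed
  probes, sex-chromosome and SNP-proximal probes, and 0.2% missing betas
  exercise every filter.
- **Dimensions** default to 20,000 probes (not 450K) so a full pipeline
  run takes seconds; the generator accepts any size.

It does **not** emulate Infinium chemistry (intensities, dye bias),
copy-number confounding, batch effects, or cell-type mixture — so green
recovery tests demonstrate correctness of the pipeline's computations
under its own assumptions, not performance on real tumor data.

# Known limitations

- **Small-group Welch tails.** With the "fewer than 2 samples excluded"
  rule, 2-vs-12 splits are tested, and the Welch–Satterthwaite p-value is
  badly anticonservative in the extreme tail there (measured
  $P(p \le 10^{-4}) \approx 6\times10^{-3}$ under a normal null — when a
  2-sample group's values are coincidentally close, $t$ explodes with
  moderate df). BH rejections live exactly in that tail, so the realized
  false-discovery proportion of the correlation stage under a global null
  is far above the nominal 0.05 whenever highly skewed splits occur. This
  is a property of the method as specified, kept for fidelity; raising
  `min_group` to 4+ largely removes it, at the cost of discarding probes
  with consistent methylation state.
- **Power ceiling of the coupling test.** At a 1.5 log2 shift, noise SD
  0.5, 14 tumors, and one BH family over ~5,000 pairs, exact
  noncentral-$t$ power to reach the BH cutoff is $\approx$ 0.84 at the
  most favorable 7/7 split and $\approx$ 0.63 averaged over admissible
  splits — roughly half of planted couplings are recoverable at these
  settings, with direction essentially never inverted on recovered pairs.
- Background correction is assumed done upstream (a documented
  precondition); expression preprocessing and batch correction are out of
  scope — the pipeline consumes an already-normalized log2 expression
  matrix.

# Problem sizes and interfaces

The default study conditions are the design above at 20,000 probes; null
calibration runs use 2,000 probes $\times$ 20 replicates (methylation
stage) and 500 pairs $\times$ 50 replicates (correlation stage). The
package's functions are the interface: the numbered scripts under
`analysis/` drive a full simulated study end to end, and `run_all()`
chains every stage under one validated configuration with a JSON run
manifest (all parameters, per-stage row counts and status), reproducible
byte-for-byte from the seed. No shell wrapper is provided — the scripts
and functions are the entry points.

```{r example, eval = FALSE}
ds <- generate_dataset(synth_config(seed = 1))
pre <- preprocess(ds$beta, ds$detp, ds$ann)
dml <- dml_pipeline(pre$beta, pre$mvals, ds$sheet)
lab <- binary_discretize(pre$beta, reference_profile(pre$beta, ds$sheet), ds$sheet)
res <- correlate(ds$expr, lab, pair_probes(ds$ann, ds$expr_map))
significant_correlations(res)
```
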