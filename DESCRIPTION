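Package: methdisc
Title: Differential Methylation and Methylation-Expression Discretization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for Infinium 450K-style DNA methylation
    beta-value matrices in a tumor-versus-normal design: probe filtering
    (detection p-values, sex chromosomes, SNP proximity), Infinium I/II
    probe-type scaling, quantile normalization and logit (M-value)
    transformation; per-probe Wilcoxon rank-sum differential-methylation
    calling with Benjamini-Hochberg correction and delta-beta thresholds;
    genomic-context summaries (chromosome, functional position, CpG-island
    relation) and complete-linkage sample clustering; and a non-linear
    "discretization" integration that labels each tumor sample
    hypermethylated (M) or hypomethylated (U) per probe relative to the
    normal-mean reference and tests paired gene-expression differences
    between the M and U groups with Welch's t-test. A seeded synthetic-data
    generator with planted differential methylation and planted
    methylation-expression couplings makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
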