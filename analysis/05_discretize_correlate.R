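#!/usr/bin/env Rscript
# Stage 5: the discretization method.  Each tumor sample is labelled
# hypermethylated (M) or hypomethylated (U) per probe against the
# normal-mean reference; Welch's t-test then compares expression between
# the M and U groups for every gene-matched probe pair, with one BH
# family across all tested pairs.

suppressPackageStartupMessages(library(methdisc))

out <- "results/correlate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

beta <- read_matrix("results/preprocess/beta_preprocessed.tsv", "beta")
expr <- read_matrix("results/data/expression.tsv", "expression")
expr_map <- read_records("results/data/expression_probe_map.tsv")
ann <- read_annotation("results/data/annotation.tsv")
sheet <- read_sample_sheet("results/data/sample_sheet.csv")
truth <- read_records("results/data/truth_couplings.tsv")

ref <- reference_profile(beta, sheet)
labels <- binary_discretize(beta, ref, sheet)
pairs <- pair_probes(ann, expr_map)
res <- correlate(expr, labels, pairs)
sig <- significant_correlations(res)

write_records(res, file.path(out, "correlations_all.tsv"))
write_records(sig, file.path(out, "correlations_significant.tsv"))

hit <- merge(sig, truth, by = c("meth_probe_id", "expr_probe_id"))
cat(sprintf(paste0(
  "Discretization (binary) over %d probes x %d tumors;",
  " %d gene-matched pairs, %d tested (%d skipped for group size < 2).\n",
  "Significant correlations (BH adj p < 0.05): %d loci",
  " (%d negative, %d positive); mean group sizes M %.1f / U %.1f.\n",
  "Planted couplings recovered: %d of %d (%.0f%%);",
  " direction inversions among recovered: %d.\n"),
  nrow(labels), ncol(labels), nrow(pairs), nrow(res),
  attr(res, "n_skipped"), nrow(sig),
  sum(sig$direction == -1L), sum(sig$direction == 1L),
  mean(res$n_M), mean(res$n_U),
  sum(hit$direction.x == hit$direction.y), nrow(truth),
  100 * sum(hit$direction.x == hit$direction.y) / nrow(truth),
  sum(hit$direction.x != hit$direction.y)))
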