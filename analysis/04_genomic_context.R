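#!/usr/bin/env Rscript
# Stage 4: DML summaries by chromosome (length-normalized), functional
# position and CpG-island context, plus complete-linkage clustering of
# samples on DML beta values.

suppressPackageStartupMessages(library(methdisc))

out <- "results/context"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

beta <- read_matrix("results/preprocess/beta_preprocessed.tsv", "beta")
ann <- read_annotation("results/data/annotation.tsv")
lengths <- read_chrom_lengths("results/data/chrom_lengths.tsv")
sheet <- read_sample_sheet("results/data/sample_sheet.csv")
dml <- read_records("results/dml/dml.tsv")

chrom <- chromosome_frequency(dml, ann, lengths)
fd <- functional_distribution(dml, ann)
cpg <- cpg_context_distribution(dml, ann)
write_records(chrom, file.path(out, "chromosome_frequency.tsv"))
write_records(fd, file.path(out, "functional_distribution.tsv"))
write_records(cpg, file.path(out, "cpg_context.tsv"))

cl <- cluster_samples(beta[dml$probe_id[dml$is_dml], ])
write_records(data.frame(sample_id = names(cl$assignment),
                         cluster = unname(cl$assignment)),
              file.path(out, "cluster_assignments.tsv"))
grp <- sheet$group[match(names(cl$assignment), sheet$sample_id)]

top <- chrom$chromosome[order(chrom$freq_total, decreasing = TRUE)][1:3]
cat(sprintf(paste0(
  "Context of %d DML:\n",
  "  highest length-normalized DML frequency on chromosomes %s.\n",
  "  functional distribution: Body %.1f%%, TSS1500 %.1f%%, TSS200 %.1f%%.\n",
  "  CpG context: Island %.1f%%, Shore %.1f%%, Shelf %.1f%%, OpenSea %.1f%%.\n",
  "Complete-linkage clustering at k = 2: adjusted Rand index vs",
  " tumor/normal = %.3f.\n"),
  sum(dml$is_dml), paste(top, collapse = ", "),
  fd$pct_all[fd$category == "Body"], fd$pct_all[fd$category == "TSS1500"],
  fd$pct_all[fd$category == "TSS200"],
  cpg$pct_all[1], cpg$pct_all[2], cpg$pct_all[3], cpg$pct_all[4],
  mclust::adjustedRandIndex(cl$assignment, grp)))
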