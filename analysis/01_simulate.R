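#!/usr/bin/env Rscript
# Stage 1: simulate a tumor/normal methylation + expression study.
#
# Emulates the target study design - 18 tumors vs 6 normal adrenal
# tissues, expression for 14 tumors, 20,000 450K-style probes - with 200
# planted DML (|delta-beta| 0.3) and 100 planted methylation-expression
# couplings (1.5 log2 units) among 5,000 null pairs.  Writes all pipeline
# inputs plus the ground-truth tables.

suppressPackageStartupMessages(library(methdisc))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

cfg <- synth_config(seed = seed)
ds <- generate_dataset(cfg)

write_matrix(ds$beta, file.path(out, "beta.tsv"))
write_matrix(ds$detp, file.path(out, "detection_p.tsv"))
write_matrix(ds$expr, file.path(out, "expression.tsv"), id_col = "expr_probe_id")
write_records(ds$expr_map, file.path(out, "expression_probe_map.tsv"))
write.table(ds$sheet, file.path(out, "sample_sheet.csv"), sep = ",",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(chromosome = names(ds$chrom_lengths),
                       length = sprintf("%.0f", ds$chrom_lengths)),
            file.path(out, "chrom_lengths.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
# the generator emits exactly one gene association per probe, so the
# manifest needs no multi-gene collapsing
g <- ds$ann$genes
g$gene[is.na(g$gene)] <- ""
ann <- merge(ds$ann$probes, g, by = "probe_id", sort = FALSE)
ann <- ann[match(rownames(ds$beta), ann$probe_id),
           c("probe_id", "chromosome", "position", "gene", "functional_group",
             "cpg_relation", "design_type", "snp_distance")]
colnames(ann)[colnames(ann) == "chromosome"] <- "chr"
colnames(ann)[colnames(ann) == "position"] <- "pos"
colnames(ann)[colnames(ann) == "functional_group"] <- "gene_group"
write_records(ann, file.path(out, "annotation.tsv"))
write_records(ds$truth$dml, file.path(out, "truth_dml.tsv"))
write_records(ds$truth$couplings, file.path(out, "truth_couplings.tsv"))

cat(sprintf(paste0(
  "Simulated %d probes x %d samples (%d tumor / %d normal), seed %d.\n",
  "Planted: %d DML (%d hyper, %d hypo), %d couplings (%d negative).\n",
  "Inputs and truth tables written under %s/.\n"),
  nrow(ds$beta), ncol(ds$beta), cfg$n_tumor, cfg$n_normal, seed,
  nrow(ds$truth$dml), sum(ds$truth$dml$direction == "hyper"),
  sum(ds$truth$dml$direction == "hypo"), nrow(ds$truth$couplings),
  sum(ds$truth$couplings$direction == -1L), out))
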