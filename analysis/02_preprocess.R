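#!/usr/bin/env Rscript
# Stage 2: probe filtering, Infinium I/II scaling, quantile normalization
# and the logit (M-value) transform, reading the stage-1 files from disk.

suppressPackageStartupMessages(library(methdisc))

ind <- "results/data"
out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

beta <- read_matrix(file.path(ind, "beta.tsv"), "beta")
detp <- read_matrix(file.path(ind, "detection_p.tsv"), "detection_p")
ann <- read_annotation(file.path(ind, "annotation.tsv"))

pre <- preprocess(beta, detp, ann)

write_matrix(pre$beta, file.path(out, "beta_preprocessed.tsv"))
write_matrix(pre$mvals, file.path(out, "mvalues.tsv"))
write_records(pre$report, file.path(out, "filter_report.tsv"))

rep <- pre$report
cat(sprintf(paste0(
  "Preprocessing: %d probes in, %d retained.\n",
  "  detection filter removed %d; annotation filter removed %d",
  " (%d sex-chromosome, %d SNP-proximal, %d unannotated).\n",
  "M-value range: [%.2f, %.2f]; all finite: %s.\n"),
  rep$input[1], rep$retained[nrow(rep)],
  rep$removed[rep$rule == "detection"], rep$removed[rep$rule == "annotation"],
  rep$removed_sex[rep$rule == "annotation"],
  rep$removed_snp[rep$rule == "annotation"],
  rep$removed_unannotated[rep$rule == "annotation"],
  min(pre$mvals, na.rm = TRUE), max(pre$mvals, na.rm = TRUE),
  all(is.finite(pre$mvals[!is.na(pre$mvals)]))))
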