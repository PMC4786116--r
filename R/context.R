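# Restrict a DML record table to called loci, returning probe_id + direction.
.dml_calls <- function(dml) {
  stopifnot(all(c("probe_id", "direction", "is_dml") %in% colnames(dml)))
  dml[dml$is_dml, c("probe_id", "direction"), drop = FALSE]
}

#' DML frequency by chromosome, normalized to chromosome length
#'
#' Counts hypo-, hyper- and total DML per chromosome and reports, alongside
#' the raw counts, a length-normalized frequency `count / length * scale`.
#' Chromosomes with zero DML still get a row.  Full precision is retained;
#' round only for display.
#'
#' @param dml DML record data.frame (rows with `is_dml` are used).
#' @param ann [probe_annotation()].
#' @param lengths named vector of chromosome lengths in bp.
#' @param scale normalization scale factor (default `1e8`).
#' @return data.frame: chromosome, n_hypo, n_hyper, n_total, freq_hypo,
#'   freq_hyper, freq_total.
#' @export
chromosome_frequency <- function(dml, ann, lengths, scale = 1e8) {
  stopifnot(inherits(ann, "probe_annotation"), all(lengths > 0))
  calls <- .dml_calls(dml)
  idx <- match(calls$probe_id, ann$probes$probe_id)
  if (anyNA(idx)) {
    warning(sprintf("%d DML probes missing from annotation; excluded",
                    sum(is.na(idx))), call. = FALSE)
    calls <- calls[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  chr <- ann$probes$chromosome[idx]
  chroms <- names(lengths)
  tab <- function(dir) {
    cnt <- table(factor(chr[calls$direction == dir], levels = chroms))
    as.integer(cnt)
  }
  n_hypo <- tab("hypo"); n_hyper <- tab("hyper")
  n_total <- n_hypo + n_hyper
  data.frame(chromosome = chroms,
             n_hypo = n_hypo, n_hyper = n_hyper, n_total = n_total,
             freq_hypo = n_hypo / lengths * scale,
             freq_hyper = n_hyper / lengths * scale,
             freq_total = n_total / lengths * scale,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Shared tally over a per-(probe, category) association table.
.context_summary <- function(calls, assoc, levels) {
  count_in <- function(ids) {
    sub <- unique(assoc[assoc$probe_id %in% ids, , drop = FALSE])
    as.integer(table(factor(sub$category, levels = levels)))
  }
  n_hyper <- count_in(calls$probe_id[calls$direction == "hyper"])
  n_hypo <- count_in(calls$probe_id[calls$direction == "hypo"])
  n_all <- count_in(calls$probe_id)
  pct <- function(n) if (sum(n) > 0) 100 * n / sum(n) else rep(0, length(n))
  data.frame(category = levels,
             n_hyper = n_hyper, pct_hyper = pct(n_hyper),
             n_hypo = n_hypo, pct_hypo = pct(n_hypo),
             n_all = n_all, pct_all = pct(n_all),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DML distribution over functional genomic positions
#'
#' Tallies DML over the functional categories TSS1500, TSS200, 5'UTR,
#' 1stExon, Body, 3'UTR and intergenic, separately for hyper-, hypo- and
#' all DML.  A probe associated with several genes contributes once per
#' *distinct* functional group, so a probe in the body of two genes counts
#' once for Body.  Percentages are over category contributions and sum to
#' 100 within each breakdown.
#'
#' @param dml DML record data.frame.
#' @param ann [probe_annotation()].
#' @return data.frame with counts and percentages per category.
#' @export
functional_distribution <- function(dml, ann) {
  stopifnot(inherits(ann, "probe_annotation"))
  calls <- .dml_calls(dml)
  assoc <- data.frame(probe_id = ann$genes$probe_id,
                      category = ann$genes$functional_group,
                      stringsAsFactors = FALSE)
  .context_summary(calls, assoc, FUNCTIONAL_GROUPS)
}

#' DML distribution over CpG-island context
#'
#' Tallies DML over Island, Shore (0-2 kb from an island), Shelf (2-4 kb)
#' and OpenSea, separately for hyper-, hypo- and all DML.  Every probe has
#' exactly one context, so `n_all` sums to the number of annotated DML.
#'
#' @param dml DML record data.frame.
#' @param ann [probe_annotation()].
#' @return data.frame with counts and percentages per category.
#' @export
cpg_context_distribution <- function(dml, ann) {
  stopifnot(inherits(ann, "probe_annotation"))
  calls <- .dml_calls(dml)
  assoc <- data.frame(probe_id = ann$probes$probe_id,
                      category = ann$probes$cpg_relation,
                      stringsAsFactors = FALSE)
  .context_summary(calls, assoc, CPG_RELATIONS)
}

#' Hierarchical clustering of samples on DML beta values
#'
#' Agglomerative clustering of samples (Euclidean distance, complete
#' linkage) on the beta matrix restricted to DML probes, as used for
#' tumor/normal separation heatmaps.  Missing values are imputed with the
#' per-probe median first (reported via a message).  Ties in merge height
#' are broken deterministically by `stats::hclust`'s ordering, so repeated
#' runs on the same input are identical.
#'
#' @param beta beta matrix restricted to the probes to cluster on.
#' @param k number of clusters for the cut (default 2, tumor vs normal).
#' @param method linkage method (default `"complete"`).
#' @return object of class `cluster_result`: list with `hclust` (the merge
#'   tree), `leaf_order` (sample IDs in dendrogram order), `assignment`
#'   (cluster label per sample at the k-cut).
#' @export
cluster_samples <- function(beta, k = 2L, method = "complete") {
  if (ncol(beta) < 3L) stop("clustering needs >= 3 samples", call. = FALSE)
  if (anyNA(beta)) {
    message(sprintf("cluster_samples: imputing %d missing values with per-probe medians",
                    sum(is.na(beta))))
    med <- apply(beta, 1L, stats::median, na.rm = TRUE)
    for (i in which(rowSums(is.na(beta)) > 0L))
      beta[i, is.na(beta[i, ])] <- med[i]
  }
  hc <- stats::hclust(stats::dist(t(beta), method = "euclidean"),
                      method = method)
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 assignment = stats::cutree(hc, k = k)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d samples, %d clusters at the cut\n",
              length(x$assignment), length(unique(x$assignment))))
  invisible(x)
}
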