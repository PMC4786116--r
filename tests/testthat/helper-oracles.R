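# Independent oracles used across tests.  These deliberately re-derive the
# statistics from first principles (enumeration, closed forms) and never
# call the code paths they check.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n1+n2, n1) group assignments of the pooled values (tie-free inputs).
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up by the textbook formula: sort ascending,
# adj_(i) = min_{j >= i} p_(j) * m / j, cap at 1, restore input order.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- rev(cummin(rev(sorted * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided permutation p-value for a mean difference, by enumeration of
# all splits of the pooled data into groups of the observed sizes.
perm_meandiff_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  combos <- utils::combn(length(pooled), n1)
  diffs <- apply(combos, 2L, function(ix)
    abs(mean(pooled[ix]) - mean(pooled[-ix])))
  mean(diffs >= obs - 1e-12)
}

# Small deterministic beta matrix with named probes/samples.
toy_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_sheet <- function(tumor, normal) {
  data.frame(sample_id = c(tumor, normal),
             group = c(rep("tumor", length(tumor)),
                       rep("normal", length(normal))),
             batch = NA_character_, stringsAsFactors = FALSE)
}

# Write a small annotation manifest file and read it back.
write_manifest_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Reduced-size generator config for fast tests; study-design group sizes
# are kept, dimensions are shrunk.
small_config <- function(...) {
  synth_config(n_probes = 800L, n_dml = 40L, n_coupled_pairs = 20L,
               n_null_pairs = 200L, n_failed_probes = 5L, ...)
}
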