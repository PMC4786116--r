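#' Normal-reference methylation profile
#'
#' Per-probe arithmetic mean beta over the normal samples — the reference
#' \eqn{\mu} against which each tumor sample is discretized.  Probes with
#' no non-missing normal value are omitted.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @return named numeric vector \eqn{\mu} in \eqn{[0,1]}.
#' @export
reference_profile <- function(beta, sheet) {
  nor <- sheet$sample_id[sheet$group == "normal"]
  nor <- nor[nor %in% colnames(beta)]
  if (length(nor) < 1L) stop("need >= 1 normal sample", call. = FALSE)
  mu <- rowMeans(beta[, nor, drop = FALSE], na.rm = TRUE)
  mu[!is.nan(mu)]
}

# Tumor sample IDs for discretization: sheet tumors present in the matrix.
.tumor_samples <- function(beta, sheet) {
  tum <- sheet$sample_id[sheet$group == "tumor"]
  tum <- tum[tum %in% colnames(beta)]
  if (length(tum) < 1L) stop("no tumor samples present in the matrix", call. = FALSE)
  tum
}

.label_matrix <- function(beta, ref, samples, mode, labeller) {
  lab <- matrix("excluded", nrow = nrow(beta), ncol = length(samples),
                dimnames = list(rownames(beta), samples))
  known <- rownames(beta) %in% names(ref)
  if (any(known)) {
    b <- beta[known, samples, drop = FALSE]
    d <- b - ref[rownames(b)]
    lab[known, ] <- labeller(d)
    lab[known, ][is.na(b)] <- "excluded"
  }
  structure(lab, mode = mode)
}

#' Binary discretization of tumor samples against the normal reference
#'
#' For each (probe, tumor sample), the sample is labelled hypermethylated
#' (`M`) when its beta exceeds the normal-mean reference \eqn{\mu} for that
#' probe (per-sample delta-beta positive) and hypomethylated (`U`) when
#' below.  A missing beta, an exact tie \eqn{\beta = \mu}, or a probe
#' absent from the reference yields `excluded`.
#'
#' @param beta beta matrix (tumor columns are selected via `sheet`).
#' @param ref reference profile from [reference_profile()].
#' @param sheet sample sheet naming the tumor samples.
#' @return character matrix (probes x tumor samples) with values in
#'   `{"M","U","excluded"}`; attribute `mode = "binary"`.
#' @export
binary_discretize <- function(beta, ref, sheet) {
  samples <- .tumor_samples(beta, sheet)
  .label_matrix(beta, ref, samples, "binary", function(d) {
    out <- matrix("excluded", nrow(d), ncol(d))
    out[!is.na(d) & d > 0] <- "M"
    out[!is.na(d) & d < 0] <- "U"
    out
  })
}

#' Ternary discretization with a neutral band
#'
#' As [binary_discretize()], but with a neutral band of half-width
#' `threshold` around the reference: `M` when \eqn{\beta - \mu >} t, `U`
#' when \eqn{\beta - \mu < -t}, `neutral` otherwise.  Neutral samples are
#' dropped from the downstream expression test.
#'
#' @param beta beta matrix.
#' @param ref reference profile.
#' @param sheet sample sheet.
#' @param threshold neutral-band half width t > 0 on the beta scale
#'   (default 0.1).
#' @return character matrix with values in `{"M","U","neutral","excluded"}`;
#'   attribute `mode = "ternary"`.
#' @export
ternary_discretize <- function(beta, ref, sheet, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("ternary threshold must be > 0", call. = FALSE)
  samples <- .tumor_samples(beta, sheet)
  .label_matrix(beta, ref, samples, "ternary", function(d) {
    out <- matrix("neutral", nrow(d), ncol(d))
    out[!is.na(d) & d > threshold] <- "M"
    out[!is.na(d) & d < -threshold] <- "U"
    out[is.na(d)] <- "excluded"
    out
  })
}

#' Pair methylation probes with expression probes by shared gene symbol
#'
#' All (methylation probe, expression probe) pairs whose gene symbols
#' match; many-to-many pairing is allowed, one pair per shared symbol.
#'
#' @param ann [probe_annotation()] carrying per-probe gene symbols.
#' @param expr_map data.frame with columns `expr_probe_id`, `gene` mapping
#'   each expression probe to one gene symbol.
#' @return data.frame: meth_probe_id, expr_probe_id, gene.
#' @export
pair_probes <- function(ann, expr_map) {
  stopifnot(inherits(ann, "probe_annotation"),
            all(c("expr_probe_id", "gene") %in% colnames(expr_map)))
  meth <- unique(ann$genes[!is.na(ann$genes$gene), c("probe_id", "gene")])
  pairs <- merge(meth, expr_map[, c("expr_probe_id", "gene")], by = "gene")
  pairs <- pairs[, c("probe_id", "expr_probe_id", "gene")]
  colnames(pairs)[1L] <- "meth_probe_id"
  pairs <- pairs[order(pairs$meth_probe_id, pairs$expr_probe_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Welch's two-sample t-test (unequal variances)
#'
#' Closed-form Welch statistic
#' \eqn{t = (\bar x_M - \bar x_U) / \sqrt{s^2_M/n_M + s^2_U/n_U}} with
#' Satterthwaite degrees of freedom and two-sided p from the t
#' distribution.  Degenerate inputs are defined rather than refused: zero
#' variance in both groups with equal means gives \eqn{t = 0, p = 1}; zero
#' variance with unequal means gives \eqn{p = 0} (with a warning), so that
#' constant expression vectors in small discretization groups cannot crash
#' a genome-wide run.
#'
#' @param x,y numeric vectors, each with >= 2 non-missing values.
#' @return list with `t_stat`, `df`, `p_value`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_test needs >= 2 non-missing values per group", call. = FALSE)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (diff == 0) return(list(t_stat = 0, df = NA_real_, p_value = 1))
    warning("zero variance with unequal means: p = 0", call. = FALSE)
    return(list(t_stat = sign(diff) * Inf, df = NA_real_, p_value = 0))
  }
  t_stat <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df = df))
}

#' Direction of a methylation-expression correlation
#'
#' `-1` (negative correlation: the hypermethylated group expresses less)
#' iff `mean_expr_M < mean_expr_U`, `+1` otherwise.  Exactly equal means
#' carry no direction and are rejected (such a pair can never be
#' significant).
#'
#' @param record one-row data.frame (or list) with `mean_expr_M` and
#'   `mean_expr_U`.
#' @return `-1` or `+1`.
#' @export
direction_of <- function(record) {
  if (record$mean_expr_M == record$mean_expr_U)
    stop("equal group means carry no correlation direction", call. = FALSE)
  if (record$mean_expr_M < record$mean_expr_U) -1 else 1
}

#' Correlate methylation state with expression across probe pairs
#'
#' For every (methylation probe, expression probe) pair, tumor expression
#' values are partitioned by the probe's discretization labels (`neutral`
#' and `excluded` samples dropped), pairs with fewer than `min_group`
#' samples in either group are skipped, Welch's t-test compares the M and
#' U groups, and BH adjustment is applied once across *all* tested pairs.
#' A pair with adjusted p below `alpha` is flagged significant; its
#' direction is `-1` when the hypermethylated group expresses less.
#'
#' @param expr expression matrix (expr probes x samples, log2 scale).
#' @param labels discretization label matrix from [binary_discretize()] or
#'   [ternary_discretize()].
#' @param pairs pair table from [pair_probes()].
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_group minimum samples per discretization group (default 2;
#'   Welch variance is undefined below that).
#' @return data.frame of tested pairs: meth_probe_id, expr_probe_id, gene,
#'   n_M, n_U, mean_expr_M, mean_expr_U, t_stat, df, raw_p, adj_p,
#'   direction, significant.  Attribute `n_skipped` counts pairs skipped
#'   for insufficient group size.
#' @export
correlate <- function(expr, labels, pairs, alpha = 0.05, min_group = 2L) {
  if (nrow(pairs) == 0L) {
    warning("empty pair list; no correlations tested", call. = FALSE)
    out <- data.frame(meth_probe_id = character(), expr_probe_id = character(),
                      gene = character(), n_M = integer(), n_U = integer(),
                      mean_expr_M = numeric(), mean_expr_U = numeric(),
                      t_stat = numeric(), df = numeric(), raw_p = numeric(),
                      adj_p = numeric(), direction = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  samples <- intersect(colnames(labels), colnames(expr))
  if (length(samples) == 0L)
    stop("labels and expression share no tumor samples", call. = FALSE)
  rows <- vector("list", nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    mp <- pairs$meth_probe_id[i]; ep <- pairs$expr_probe_id[i]
    if (!mp %in% rownames(labels) || !ep %in% rownames(expr)) {
      skipped <- skipped + 1L; next
    }
    lab <- labels[mp, samples]
    ev <- expr[ep, samples]
    ok <- !is.na(ev)
    xm <- ev[ok & lab == "M"]; xu <- ev[ok & lab == "U"]
    if (length(xm) < min_group || length(xu) < min_group) {
      skipped <- skipped + 1L; next
    }
    w <- welch_test(xm, xu)
    rows[[i]] <- data.frame(
      meth_probe_id = mp, expr_probe_id = ep, gene = pairs$gene[i],
      n_M = length(xm), n_U = length(xu),
      mean_expr_M = mean(xm), mean_expr_U = mean(xu),
      t_stat = w$t_stat, df = w$df, raw_p = w$p_value,
      stringsAsFactors = FALSE)
  }
  tested <- do.call(rbind, rows)
  if (is.null(tested)) {
    warning("no pairs had sufficient group sizes", call. = FALSE)
    return(correlate(expr, labels, pairs[0, , drop = FALSE], alpha, min_group))
  }
  tested$adj_p <- bh_adjust(tested$raw_p)
  d <- sign(tested$mean_expr_M - tested$mean_expr_U)
  tested$direction <- ifelse(d == 0, NA_integer_, ifelse(d < 0, -1L, 1L))
  tested$significant <- tested$adj_p < alpha & !is.na(tested$direction)
  rownames(tested) <- NULL
  attr(tested, "n_skipped") <- skipped
  tested
}

#' Filter a correlation table to the significant records
#'
#' @param records output of [correlate()].
#' @return the significant rows.
#' @export
significant_correlations <- function(records) {
  records[records$significant, , drop = FALSE]
}
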