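#' Remove probes failing the detection p-value rule
#'
#' A probe is removed when the fraction of samples with detection
#' p > `p_threshold` is at least `sample_fraction` (so a probe failing in
#' exactly 25% of samples is removed at the defaults).
#'
#' @param beta beta matrix (probes x samples).
#' @param detp detection p-value matrix, same dimensions and dimnames.
#' @param p_threshold detection p-value above which a measurement counts as
#'   failed (default 0.05).
#' @param sample_fraction fraction of failed samples that triggers removal
#'   (default 0.25).
#' @return list with `beta` (filtered matrix) and `report` (a one-row
#'   data.frame of counts; see [filter_report()]).
#' @export
filter_detection <- function(beta, detp, p_threshold = 0.05,
                             sample_fraction = 0.25) {
  if (!identical(dim(beta), dim(detp)) ||
      !identical(dimnames(beta), dimnames(detp)))
    stop("beta and detection-p matrices must share dimensions and dimnames",
         call. = FALSE)
  failed <- rowMeans(detp > p_threshold, na.rm = TRUE)
  drop <- failed >= sample_fraction
  list(beta = beta[!drop, , drop = FALSE],
       report = filter_report(rule = "detection",
                              input = nrow(beta),
                              removed = sum(drop)))
}

#' Remove sex-chromosome, SNP-proximal and unannotated probes
#'
#' Probes on chromosomes X or Y are removed, as are probes within `snp_bp`
#' base pairs of a catalogued SNP (boundary inclusive: `snp_distance <=
#' snp_bp` is removed).  Probes absent from the annotation are removed and
#' counted separately.
#'
#' @param beta beta matrix.
#' @param ann [probe_annotation()] object.
#' @param snp_bp SNP proximity threshold in bp (default 10).
#' @return list with `beta` and `report`.
#' @export
filter_annotation <- function(beta, ann, snp_bp = 10) {
  stopifnot(inherits(ann, "probe_annotation"))
  idx <- match(rownames(beta), ann$probes$probe_id)
  unannotated <- is.na(idx)
  chr <- ann$probes$chromosome[idx]
  snp <- ann$probes$snp_distance[idx]
  sex <- !unannotated & chr %in% c("X", "Y")
  near_snp <- !unannotated & !is.na(snp) & snp <= snp_bp
  drop <- unannotated | sex | near_snp
  rep <- filter_report(rule = "annotation", input = nrow(beta),
                       removed = sum(drop))
  rep$removed_sex <- sum(sex)
  rep$removed_snp <- sum(near_snp & !sex)
  rep$removed_unannotated <- sum(unannotated)
  list(beta = beta[!drop, , drop = FALSE], report = rep)
}

#' One-row filter report
#'
#' @param rule label of the filtering rule.
#' @param input number of probes before filtering.
#' @param removed number of probes removed.
#' @return data.frame with columns rule, input, removed, retained
#'   (`removed + retained == input` by construction).
#' @export
filter_report <- function(rule, input, removed) {
  data.frame(rule = rule, input = as.integer(input),
             removed = as.integer(removed),
             retained = as.integer(input - removed),
             removed_sex = NA_integer_, removed_snp = NA_integer_,
             removed_unannotated = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Scale Infinium II probes onto the type-I distribution
#'
#' Within each sample, type-II beta values are quantile-mapped onto the
#' empirical distribution of that sample's type-I beta values (linear
#' interpolation between type-I order statistics); type-I values are left
#' unchanged.  This balances the systematically compressed dynamic range of
#' Infinium II chemistry against type I.  The map is monotone, so the
#' within-sample ranking of type-II probes is preserved, and output stays
#' in \eqn{[0,1]}.
#'
#' @param beta beta matrix.
#' @param ann [probe_annotation()] with `design_type` per probe.
#' @return scaled beta matrix (same dimnames).
#' @export
scale_design_types <- function(beta, ann) {
  stopifnot(inherits(ann, "probe_annotation"))
  idx <- match(rownames(beta), ann$probes$probe_id)
  if (any(is.na(idx)))
    stop("every probe must be annotated with a design type before scaling",
         call. = FALSE)
  type <- ann$probes$design_type[idx]
  is2 <- type == "II"
  if (!any(is2)) return(beta)  # nothing to scale
  out <- beta
  for (j in seq_len(ncol(beta))) {
    x1 <- beta[!is2, j]; x1 <- x1[!is.na(x1)]
    x2 <- beta[is2, j]
    ok2 <- !is.na(x2)
    if (length(x1) < 2L || sum(ok2) < 2L) {
      warning(sprintf("sample '%s': fewer than 2 probes of a design type; scaling skipped",
                      colnames(beta)[j]), call. = FALSE)
      next
    }
    # empirical quantile map: type-II value at quantile q -> type-I quantile q;
    # with this grid, identical type-I/II distributions map to the identity
    q <- (rank(x2[ok2], ties.method = "average") - 1) / (sum(ok2) - 1)
    mapped <- stats::quantile(x1, probs = q, names = FALSE, type = 7)
    v <- x2
    v[ok2] <- mapped
    out[is2, j] <- v
  }
  out
}

#' Quantile-normalize a beta matrix across samples
#'
#' Standard across-sample quantile normalization: after normalization every
#' sample's sorted value vector equals the mean of the samples' sorted
#' vectors, and within-sample ranks are preserved.  Missing values stay
#' missing and are excluded from the reference distribution (non-missing
#' values are interpolated onto the common quantile grid).  Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param beta beta matrix with >= 2 samples (a single sample is returned
#'   unchanged with a warning).
#' @param ties passed to limma (average over ties; default TRUE).
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(beta, ties = TRUE) {
  if (ncol(beta) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged",
            call. = FALSE)
    return(beta)
  }
  out <- limma::normalizeQuantiles(beta, ties = ties)
  dimnames(out) <- dimnames(beta)
  out
}

#' Logit (M-value) transformation of beta values
#'
#' Beta values are clamped to \eqn{[\epsilon, 1-\epsilon]} and transformed
#' to \eqn{M = \log_2(\beta / (1-\beta))}.  The clamp keeps M-values finite
#' (roughly \eqn{[-10, 10]} at the default \eqn{\epsilon = 10^{-3}}); the
#' transform converts the heteroscedastic, bounded beta scale to an
#' approximately Gaussian scale suitable for rank and t statistics.
#'
#' @param beta beta matrix (or numeric vector) in \eqn{[0,1]}.
#' @param epsilon clamp width, must lie in (0, 0.5); default `1e-3`.
#' @return M-value matrix (or vector); missing values stay missing.
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Inverse of [beta_to_m()]
#'
#' @param m M-values.
#' @return beta values in (0,1).
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Full methylation preprocessing
#'
#' Chains the paper-style preprocessing on an already background-corrected
#' beta matrix: detection filter, sex-chromosome/SNP/annotation filter,
#' Infinium I/II probe scaling, across-sample quantile normalization, and
#' the logit (M-value) transform.
#'
#' @param beta beta matrix.
#' @param detp detection p-value matrix (or NULL to skip that filter).
#' @param ann [probe_annotation()].
#' @param p_threshold,sample_fraction detection rule, see [filter_detection()].
#' @param snp_bp SNP proximity threshold, see [filter_annotation()].
#' @param type_scaling apply [scale_design_types()] (default TRUE).
#' @param quantile apply [quantile_normalize()] (default TRUE).
#' @param epsilon logit clamp, see [beta_to_m()].
#' @return list with `beta` (filtered+normalized), `mvals`, and `report`
#'   (row-bound filter reports).
#' @export
preprocess <- function(beta, detp = NULL, ann,
                       p_threshold = 0.05, sample_fraction = 0.25,
                       snp_bp = 10, type_scaling = TRUE, quantile = TRUE,
                       epsilon = 1e-3) {
  validate_beta_matrix(beta)
  reports <- list()
  if (!is.null(detp)) {
    st <- filter_detection(beta, detp, p_threshold, sample_fraction)
    beta <- st$beta
    reports <- c(reports, list(st$report))
  }
  st <- filter_annotation(beta, ann, snp_bp)
  beta <- st$beta
  reports <- c(reports, list(st$report))
  if (type_scaling) beta <- scale_design_types(beta, ann)
  if (quantile) beta <- quantile_normalize(beta)
  list(beta = beta,
       mvals = beta_to_m(beta, epsilon),
       report = do.call(rbind, reports))
}
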