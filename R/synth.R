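# Natural-log logit/logistic used by the generator (monotone-equivalent to
# the log2 M-value transform used downstream).
.logit <- function(p) log(p / (1 - p))
.logistic <- function(x) 1 / (1 + exp(-x))

# Approximate hg19 chromosome lengths (bp), autosomes + X/Y.
.CHROM_LENGTHS <- c(
  "1" = 249e6, "2" = 243e6, "3" = 198e6, "4" = 191e6, "5" = 181e6,
  "6" = 171e6, "7" = 159e6, "8" = 146e6, "9" = 141e6, "10" = 136e6,
  "11" = 135e6, "12" = 134e6, "13" = 115e6, "14" = 107e6, "15" = 103e6,
  "16" = 90e6, "17" = 81e6, "18" = 78e6, "19" = 59e6, "20" = 63e6,
  "21" = 48e6, "22" = 51e6, "X" = 155e6, "Y" = 59e6)

#' Configuration for the synthetic methylation + expression generator
#'
#' Defaults mirror the study design the pipeline targets: 18 tumors versus
#' 6 normals with expression available for 14 tumors, 20,000 array probes,
#' 200 planted differentially methylated loci at a target
#' \eqn{|\Delta\beta|} of 0.3 (40% hypermethylated), and 100 planted
#' methylation-expression couplings of 1.5 log2 units (60% negative) among
#' 5,000 null probe pairs.  Methylation noise is logit-normal (SD 0.5 on
#' the natural-log logit scale); expression noise is Gaussian with SD 0.5
#' log2 units.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_expr_tumor tumors with expression data (first `n_expr_tumor`
#'   tumors).
#' @param n_probes methylation probes.
#' @param n_dml planted DML count.
#' @param target_abs_delta_beta planted \eqn{|\Delta\beta|} on the beta
#'   scale (tumor minus normal group mean).
#' @param dml_hyper_fraction fraction of planted DML that are
#'   hypermethylated.
#' @param n_coupled_pairs planted methylation-expression couplings.
#' @param n_null_pairs expression probes paired to uncoupled methylation
#'   probes.
#' @param coupling_shift_log2 expression shift magnitude for coupled pairs
#'   (log2 units).
#' @param coupling_negative_fraction fraction of couplings with negative
#'   direction (hypermethylated samples express less).
#' @param coupling_delta_beta per-sample beta separation planted between a
#'   coupled probe's M and U samples and the normal reference.
#' @param coupling_min_group smallest planted M or U group among the
#'   expression tumors.
#' @param meth_logit_sd methylation noise SD (natural-log logit scale).
#' @param expr_sd expression noise SD (log2 units).
#' @param cpg_props named proportions over Island/Shore/Shelf/OpenSea.
#' @param type2_fraction fraction of Infinium II probes.
#' @param type2_attenuation compression of type-II betas toward 0.5 (1 =
#'   no compression), emulating the narrower type-II dynamic range.
#' @param sex_probe_fraction fraction of filler probes placed on X/Y.
#' @param snp_probe_fraction fraction of filler probes given a nearby SNP
#'   (distance 0-50 bp).
#' @param n_failed_probes probes planted with widespread detection failure.
#' @param detection_fail_rate per-cell sporadic detection-failure rate.
#' @param missing_rate per-cell missing-beta rate.
#' @param intergenic_fraction filler probes with no gene association.
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_tumor = 18L, n_normal = 6L, n_expr_tumor = 14L,
                         n_probes = 20000L, n_dml = 200L,
                         target_abs_delta_beta = 0.3,
                         dml_hyper_fraction = 0.4,
                         n_coupled_pairs = 100L, n_null_pairs = 5000L,
                         coupling_shift_log2 = 1.5,
                         coupling_negative_fraction = 0.6,
                         coupling_delta_beta = 0.25,
                         coupling_min_group = 4L,
                         meth_logit_sd = 0.5, expr_sd = 0.5,
                         cpg_props = c(Island = 0.31, Shore = 0.23,
                                       Shelf = 0.10, OpenSea = 0.36),
                         type2_fraction = 0.7, type2_attenuation = 0.9,
                         sex_probe_fraction = 0.03,
                         snp_probe_fraction = 0.01,
                         n_failed_probes = 20L,
                         detection_fail_rate = 0.002,
                         missing_rate = 0.002,
                         intergenic_fraction = 0.1,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_dml <= cfg$n_probes,
            cfg$n_dml + cfg$n_coupled_pairs + cfg$n_null_pairs +
              cfg$n_failed_probes <= cfg$n_probes,
            cfg$n_expr_tumor <= cfg$n_tumor,
            cfg$coupling_min_group * 2L <= cfg$n_expr_tumor,
            all(unlist(cfg[c("target_abs_delta_beta", "dml_hyper_fraction",
                             "coupling_negative_fraction", "type2_fraction",
                             "missing_rate", "detection_fail_rate")]) >= 0),
            abs(sum(cfg$cpg_props) - 1) < 1e-8)
  structure(cfg, class = "synth_config")
}

#' Logit-scale shift achieving a target beta-scale group difference
#'
#' Solves for the shift \eqn{s} such that
#' \eqn{E[\mathrm{logistic}(\mathrm{logit}(b) + s + N(0,\sigma))] -
#' E[\mathrm{logistic}(\mathrm{logit}(b) + N(0,\sigma))]} equals
#' `target_delta` (to \eqn{10^{-3}}), by numeric integration of the
#' logit-normal mean and root finding.  In the \eqn{\sigma \to 0} limit
#' this is \eqn{\mathrm{logit}(b + \mathrm{target}) - \mathrm{logit}(b)}.
#'
#' @param baseline_beta baseline beta in (0,1).
#' @param target_delta desired beta-scale difference (signed); baseline +
#'   target must stay inside (0,1).
#' @param sd logit-scale noise SD.
#' @return shift in natural-log logit units.
#' @export
calibrate_shift <- function(baseline_beta, target_delta, sd) {
  if (target_delta == 0) return(0)
  if (baseline_beta <= 0 || baseline_beta >= 1 ||
      baseline_beta + target_delta <= 0 || baseline_beta + target_delta >= 1)
    stop(sprintf("target delta-beta %g unachievable at baseline %g",
                 target_delta, baseline_beta), call. = FALSE)
  m0 <- .logit(baseline_beta)
  ev <- function(m) {
    if (sd == 0) return(.logistic(m))
    stats::integrate(function(z) .logistic(m + sd * z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-9)$value
  }
  base <- ev(m0)
  f <- function(s) ev(m0 + s) - base - target_delta
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-6)$root
}

#' Generate a synthetic methylation + expression dataset with planted truth
#'
#' Emits every input the pipeline consumes — beta and detection-p matrices,
#' a log2 expression matrix with probe-to-gene map, a 450K-style probe
#' annotation, sample sheet and chromosome lengths — plus truth tables for
#' the planted differential methylation and methylation-expression
#' couplings.  Per probe, a baseline mean beta is drawn from a bimodal
#' (low/high methylation) mixture; sample values are baseline + Gaussian
#' noise on the logit scale, mapped back through the logistic, so betas are
#' strictly inside (0,1) and the pipeline's logit transform Gaussianizes
#' them exactly.  Planted DML shift tumor logit means by a per-probe shift
#' solved with [calibrate_shift()] so the expected beta-scale
#' \eqn{\Delta\beta} hits the configured target; coupled expression probes
#' are shifted by the coupling magnitude in tumors whose planted
#' methylation state is M.  Type-II probes are mildly compressed toward
#' 0.5 to emulate Infinium II chemistry (undone by probe-type scaling in
#' preprocessing).  Fully reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with elements `beta`, `detp`, `expr`, `expr_map`, `ann`,
#'   `sheet`, `chrom_lengths`, `truth` (list: `dml`, `couplings`, `states`)
#'   and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  c_ <- config
  set.seed(c_$seed)

  tumors <- sprintf("ACC_%02d", seq_len(c_$n_tumor))
  normals <- sprintf("NORM_%02d", seq_len(c_$n_normal))
  samples <- c(tumors, normals)
  expr_tumors <- tumors[seq_len(c_$n_expr_tumor)]
  probes <- sprintf("cg%08d", seq_len(c_$n_probes))

  # --- roles: planted DML, coupled, detection-failed, filler -------------
  idx_all <- seq_len(c_$n_probes)
  idx_dml <- seq_len(c_$n_dml)
  idx_coupled <- seq_len(c_$n_coupled_pairs) + c_$n_dml
  idx_null_pair <- seq_len(c_$n_null_pairs) + c_$n_dml + c_$n_coupled_pairs
  idx_failed <- seq_len(c_$n_failed_probes) + c_$n_dml + c_$n_coupled_pairs +
    c_$n_null_pairs
  special <- c(idx_dml, idx_coupled, idx_null_pair, idx_failed)

  # --- baselines: bimodal logit-normal mixture ---------------------------
  draw_baseline <- function(n) {
    high <- stats::runif(n) < 0.45
    m <- ifelse(high, stats::rnorm(n, .logit(0.85), 0.8),
                stats::rnorm(n, .logit(0.10), 0.8))
    .logistic(m)
  }
  baseline <- draw_baseline(c_$n_probes)
  # planted probes need headroom for their shift; re-draw until achievable
  ensure_headroom <- function(i, deltas) {
    ok <- function(b) all(b + c(0, deltas) > 0.02 & b + c(0, deltas) < 0.98)
    tries <- 0L
    while (!ok(baseline[i])) {
      baseline[i] <<- draw_baseline(1L)
      tries <- tries + 1L
      if (tries > 500L) stop("could not draw a feasible baseline", call. = FALSE)
    }
  }
  n_hyper <- round(c_$n_dml * c_$dml_hyper_fraction)
  dml_dir <- rep("hypo", c_$n_dml)
  if (n_hyper > 0) dml_dir[sample.int(c_$n_dml, n_hyper)] <- "hyper"
  dml_delta <- ifelse(dml_dir == "hyper", 1, -1) * c_$target_abs_delta_beta
  for (k in seq_along(idx_dml)) ensure_headroom(idx_dml[k], dml_delta[k])
  for (i in idx_coupled)
    ensure_headroom(i, c(-1, 1) * c_$coupling_delta_beta)

  # --- per-probe logit means, with planted tumor shifts ------------------
  m0 <- .logit(baseline)
  sd <- c_$meth_logit_sd
  dml_shift <- vapply(seq_along(idx_dml), function(k)
    calibrate_shift(baseline[idx_dml[k]], dml_delta[k], sd), numeric(1))
  coup_shift_m <- vapply(idx_coupled, function(i)
    calibrate_shift(baseline[i], c_$coupling_delta_beta, sd), numeric(1))
  coup_shift_u <- vapply(idx_coupled, function(i)
    calibrate_shift(baseline[i], -c_$coupling_delta_beta, sd), numeric(1))

  # planted M/U states for coupled probes across ALL tumors; group-size
  # floor enforced among the expression tumors
  states <- matrix("U", nrow = length(idx_coupled), ncol = c_$n_tumor,
                   dimnames = list(probes[idx_coupled], tumors))
  n_m_expr <- sample(seq.int(c_$coupling_min_group,
                             c_$n_expr_tumor - c_$coupling_min_group),
                     length(idx_coupled), replace = TRUE)
  for (k in seq_along(idx_coupled)) {
    m_expr <- sample.int(c_$n_expr_tumor, n_m_expr[k])
    states[k, m_expr] <- "M"
    rest <- setdiff(seq_len(c_$n_tumor), seq_len(c_$n_expr_tumor))
    if (length(rest) > 0)
      states[k, rest[stats::runif(length(rest)) < 0.5]] <- "M"
  }

  mean_logit <- matrix(m0, nrow = c_$n_probes, ncol = length(samples),
                       dimnames = list(probes, samples))
  mean_logit[idx_dml, tumors] <- mean_logit[idx_dml, tumors] + dml_shift
  for (k in seq_along(idx_coupled)) {
    i <- idx_coupled[k]
    is_m <- states[k, ] == "M"
    mean_logit[i, tumors] <- m0[i] + ifelse(is_m, coup_shift_m[k], coup_shift_u[k])
  }

  beta <- .logistic(mean_logit +
                    matrix(stats::rnorm(length(mean_logit), 0, sd),
                           nrow = c_$n_probes))

  # --- annotation --------------------------------------------------------
  design <- ifelse(stats::runif(c_$n_probes) < c_$type2_fraction, "II", "I")
  if (c_$type2_attenuation < 1) {
    is2 <- design == "II"
    beta[is2, ] <- 0.5 + c_$type2_attenuation * (beta[is2, ] - 0.5)
  }

  chrom <- sample(as.character(1:22), c_$n_probes, replace = TRUE)
  filler <- setdiff(idx_all, special)
  sex <- filler[stats::runif(length(filler)) < c_$sex_probe_fraction]
  chrom[sex] <- sample(c("X", "Y"), length(sex), replace = TRUE)
  pos <- floor(stats::runif(c_$n_probes) * (.CHROM_LENGTHS[chrom] - 1000)) + 1
  snp_dist <- rep(NA_real_, c_$n_probes)
  snp_hit <- filler[stats::runif(length(filler)) < c_$snp_probe_fraction]
  snp_dist[snp_hit] <- floor(stats::runif(length(snp_hit), 0, 51))
  cpg <- sample(names(c_$cpg_props), c_$n_probes, replace = TRUE,
                prob = c_$cpg_props)

  gene <- sprintf("G%06d", idx_all)
  intergenic <- filler[stats::runif(length(filler)) < c_$intergenic_fraction]
  gene[intergenic] <- NA_character_
  groups_nonint <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
  fg <- sample(groups_nonint, c_$n_probes, replace = TRUE,
               prob = c(0.17, 0.12, 0.12, 0.06, 0.45, 0.08))
  fg[is.na(gene)] <- "intergenic"

  ann <- probe_annotation(
    probes = data.frame(probe_id = probes, chromosome = chrom, position = pos,
                        cpg_relation = cpg, design_type = design,
                        snp_distance = snp_dist, stringsAsFactors = FALSE),
    genes = data.frame(probe_id = probes, gene = gene, functional_group = fg,
                       stringsAsFactors = FALSE))

  # --- detection p and missingness --------------------------------------
  detp <- matrix(stats::runif(length(beta), 0, 0.01),
                 nrow = c_$n_probes, dimnames = dimnames(beta))
  sporadic <- stats::runif(length(detp)) < c_$detection_fail_rate
  detp[sporadic] <- stats::runif(sum(sporadic), 0.05, 1)
  for (i in idx_failed) {
    fail_cols <- sample(length(samples), ceiling(0.4 * length(samples)))
    detp[i, fail_cols] <- stats::runif(length(fail_cols), 0.1, 1)
  }
  miss <- stats::runif(length(beta)) < c_$missing_rate
  beta[miss] <- NA_real_

  # --- expression --------------------------------------------------------
  pair_idx <- c(idx_coupled, idx_null_pair)
  expr_probes <- sprintf("ex%06d", seq_along(pair_idx))
  expr_map <- data.frame(expr_probe_id = expr_probes, gene = gene[pair_idx],
                         stringsAsFactors = FALSE)
  expr_base <- stats::runif(length(pair_idx), 6, 12)
  expr <- matrix(expr_base +
                 stats::rnorm(length(pair_idx) * c_$n_expr_tumor, 0, c_$expr_sd),
                 nrow = length(pair_idx), ncol = c_$n_expr_tumor,
                 dimnames = list(expr_probes, expr_tumors))
  n_neg <- round(c_$n_coupled_pairs * c_$coupling_negative_fraction)
  coup_dir <- rep(1L, c_$n_coupled_pairs)
  if (n_neg > 0) coup_dir[sample.int(c_$n_coupled_pairs, n_neg)] <- -1L
  for (k in seq_len(c_$n_coupled_pairs)) {
    is_m <- states[k, expr_tumors] == "M"
    expr[k, is_m] <- expr[k, is_m] + coup_dir[k] * c_$coupling_shift_log2
  }

  truth_dml <- data.frame(probe_id = probes[idx_dml], direction = dml_dir,
                          target_delta_beta = dml_delta, logit_shift = dml_shift,
                          stringsAsFactors = FALSE)
  truth_coup <- data.frame(meth_probe_id = probes[idx_coupled],
                           expr_probe_id = expr_probes[seq_len(c_$n_coupled_pairs)],
                           gene = gene[idx_coupled], direction = coup_dir,
                           shift_log2 = coup_dir * c_$coupling_shift_log2,
                           n_M_expr = n_m_expr, stringsAsFactors = FALSE)

  sheet <- data.frame(sample_id = samples,
                      group = c(rep("tumor", c_$n_tumor),
                                rep("normal", c_$n_normal)),
                      batch = NA_character_, stringsAsFactors = FALSE)

  list(beta = beta, detp = detp, expr = expr, expr_map = expr_map, ann = ann,
       sheet = sheet, chrom_lengths = .CHROM_LENGTHS,
       truth = list(dml = truth_dml, couplings = truth_coup, states = states),
       config = config)
}
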