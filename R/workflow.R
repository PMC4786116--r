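#' Configuration for a full pipeline run
#'
#' Collects every threshold the pipeline stages expose, plus the output
#' directory and seed.  Values are validated here, before any stage runs.
#' Precedence is caller > default; the full resolved configuration is
#' recorded in the run manifest.
#'
#' @param out_dir directory for stage outputs (created if absent).
#' @param seed RNG seed for the whole run.
#' @param synth named list of [synth_config()] overrides (its `seed`
#'   defaults to `seed`).
#' @param p_threshold,sample_fraction detection filter rule.
#' @param snp_bp SNP-proximity filter threshold (bp).
#' @param type_scaling,quantile toggles for probe-type scaling and
#'   quantile normalization.
#' @param epsilon logit clamp.
#' @param alpha DML adjusted-p threshold.
#' @param min_delta DML \eqn{|\Delta\beta|} threshold.
#' @param discretize_mode `"binary"` or `"ternary"`.
#' @param ternary_threshold neutral-band half width for ternary mode.
#' @param corr_alpha correlation adjusted-p threshold.
#' @param min_group minimum discretization group size.
#' @param scale chromosome-frequency normalization scale.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, synth = list(),
                       p_threshold = 0.05, sample_fraction = 0.25,
                       snp_bp = 10, type_scaling = TRUE, quantile = TRUE,
                       epsilon = 1e-3, alpha = 0.05, min_delta = 0.2,
                       discretize_mode = c("binary", "ternary"),
                       ternary_threshold = 0.1, corr_alpha = 0.05,
                       min_group = 2L, scale = 1e8) {
  discretize_mode <- match.arg(discretize_mode)
  check01 <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi)
      stop(sprintf("%s must be a number in [%g, %g]", name, lo, hi),
           call. = FALSE)
  }
  check01(p_threshold, "p_threshold"); check01(sample_fraction, "sample_fraction")
  check01(alpha, "alpha"); check01(min_delta, "min_delta")
  check01(corr_alpha, "corr_alpha")
  check01(epsilon, "epsilon", 1e-12, 0.4999)
  if (snp_bp < 0) stop("snp_bp must be >= 0", call. = FALSE)
  if (ternary_threshold <= 0) stop("ternary_threshold must be > 0", call. = FALSE)
  if (min_group < 2L) stop("min_group must be >= 2", call. = FALSE)
  if (!"seed" %in% names(synth)) synth$seed <- seed
  cfg <- as.list(environment())
  cfg$check01 <- NULL
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Chains simulate, preprocess, differential methylation, genomic-context
#' summaries, discretization and methylation-expression correlation, with
#' shared configuration and a run manifest.  Each stage's output row counts
#' are recorded; a failing stage halts the run with a stage-named error,
#' and the (partial) manifest is still written.  Given the same
#' configuration and seed, all outputs are reproducible.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly: list with `parameters`, `stages`
#'   (data.frame: stage, status, n_in, n_out, elapsed_s), `success`, and
#'   the in-memory stage results under `results`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- data.frame(stage = character(), status = character(),
                       n_in = integer(), n_out = integer(),
                       elapsed_s = numeric(), stringsAsFactors = FALSE)
  results <- list()
  manifest_path <- file.path(config$out_dir, "manifest.json")
  write_manifest <- function(success, failed_stage = NULL) {
    man <- list(package = "methdisc",
                version = as.character(utils::packageVersion("methdisc")),
                parameters = unclass(config)[setdiff(names(config), "synth")],
                synth_parameters = config$synth,
                stages = stages, success = success)
    if (!is.null(failed_stage)) man$failed_stage <- failed_stage
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    man
  }
  run_stage <- function(name, n_in, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stages[nrow(stages) + 1L, ] <<- list(name, "failed", as.integer(n_in),
                                           NA_integer_,
                                           proc.time()[["elapsed"]] - t0)
      write_manifest(FALSE, failed_stage = name)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages[nrow(stages) + 1L, ] <<- list(name, "ok", as.integer(n_in),
                                         as.integer(res$n_out),
                                         round(proc.time()[["elapsed"]] - t0, 3))
    res$value
  }
  out <- function(name) file.path(config$out_dir, name)

  # --- simulate ----------------------------------------------------------
  ds <- run_stage("simulate", 0L, function() {
    ds <- generate_dataset(do.call(synth_config, config$synth))
    write_matrix(ds$beta, out("sim_beta.tsv"))
    write_matrix(ds$expr, out("sim_expression.tsv"), id_col = "expr_probe_id")
    utils::write.table(ds$sheet, out("sample_sheet.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    write_records(ds$truth$dml, out("truth_dml.tsv"))
    write_records(ds$truth$couplings, out("truth_couplings.tsv"))
    list(value = ds, n_out = nrow(ds$beta))
  })

  # --- preprocess --------------------------------------------------------
  pre <- run_stage("preprocess", nrow(ds$beta), function() {
    pre <- preprocess(ds$beta, ds$detp, ds$ann,
                      p_threshold = config$p_threshold,
                      sample_fraction = config$sample_fraction,
                      snp_bp = config$snp_bp,
                      type_scaling = config$type_scaling,
                      quantile = config$quantile, epsilon = config$epsilon)
    write_matrix(pre$beta, out("beta_preprocessed.tsv"))
    write_matrix(pre$mvals, out("mvalues.tsv"))
    write_records(pre$report, out("filter_report.tsv"))
    list(value = pre, n_out = nrow(pre$beta))
  })

  # --- differential methylation ------------------------------------------
  dml <- run_stage("dml", nrow(pre$beta), function() {
    dml <- dml_pipeline(pre$beta, pre$mvals, ds$sheet,
                        alpha = config$alpha, min_delta = config$min_delta)
    write_records(dml, out("dml.tsv"))
    list(value = dml, n_out = sum(dml$is_dml))
  })

  # --- context summaries + clustering ------------------------------------
  ctx <- run_stage("summarize", sum(dml$is_dml), function() {
    chrom <- chromosome_frequency(dml, ds$ann, ds$chrom_lengths,
                                  scale = config$scale)
    fun <- functional_distribution(dml, ds$ann)
    cpg <- cpg_context_distribution(dml, ds$ann)
    write_records(chrom, out("chromosome_frequency.tsv"))
    write_records(fun, out("functional_distribution.tsv"))
    write_records(cpg, out("cpg_context.tsv"))
    clus <- NULL
    if (sum(dml$is_dml) >= 2L) {
      clus <- cluster_samples(pre$beta[dml$probe_id[dml$is_dml], , drop = FALSE])
      write_records(data.frame(sample_id = names(clus$assignment),
                               cluster = unname(clus$assignment)),
                    out("cluster_assignments.tsv"))
    }
    list(value = list(chromosome = chrom, functional = fun, cpg = cpg,
                      clustering = clus),
         n_out = nrow(chrom) + nrow(fun) + nrow(cpg))
  })

  # --- discretize --------------------------------------------------------
  labels <- run_stage("discretize", nrow(pre$beta), function() {
    ref <- reference_profile(pre$beta, ds$sheet)
    lab <- if (config$discretize_mode == "binary") {
      binary_discretize(pre$beta, ref, ds$sheet)
    } else {
      ternary_discretize(pre$beta, ref, ds$sheet,
                         threshold = config$ternary_threshold)
    }
    write_matrix_chr <- function(m, path) {
      df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE)
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_matrix_chr(lab, out("discretization_labels.tsv"))
    list(value = lab, n_out = nrow(lab))
  })

  # --- correlate ---------------------------------------------------------
  corr <- run_stage("correlate", nrow(labels), function() {
    pairs <- pair_probes(ds$ann, ds$expr_map)
    corr <- correlate(ds$expr, labels, pairs,
                      alpha = config$corr_alpha, min_group = config$min_group)
    write_records(corr, out("correlations.tsv"))
    write_records(significant_correlations(corr),
                  out("correlations_significant.tsv"))
    list(value = corr, n_out = sum(corr$significant))
  })

  man <- write_manifest(TRUE)
  man$results <- list(dataset = ds, preprocessed = pre, dml = dml,
                      context = ctx, labels = labels, correlations = corr)
  invisible(man)
}
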