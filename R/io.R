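# Delimiter by file extension: .csv comma, anything else tab.
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# "NA" (any case) and empty cells encode missing values; this mirrors the
# TCGA level-3 convention.  Missing is stored as NA, never as 0.
.parse_numeric_cells <- function(x, what, probe, sample) {
  raw <- trimws(x)
  miss <- raw == "" | toupper(raw) == "NA"
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!miss & is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable %s value '%s' at probe '%s', sample '%s'",
                 what, raw[bad[1L]], probe[bad[1L]], sample[bad[1L]]),
         call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}

.check_unique <- function(ids, what) {
  d <- duplicated(ids)
  if (any(d)) {
    stop(sprintf("duplicate %s '%s'", what, ids[which(d)[1L]]), call. = FALSE)
  }
  invisible(ids)
}

#' Validate a beta-value matrix
#'
#' Checks that all non-missing entries lie in \eqn{[0,1]} and that probe and
#' sample identifiers are unique.  Errors name the first offending cell.
#'
#' @param beta numeric matrix, probes in rows, samples in columns, with
#'   `rownames` (probe IDs) and `colnames` (sample IDs).
#' @return the matrix, invisibly.
#' @export
validate_beta_matrix <- function(beta) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix must have probe rownames and sample colnames", call. = FALSE)
  .check_unique(rownames(beta), "probe ID")
  .check_unique(colnames(beta), "sample ID")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value %g outside [0,1] at probe '%s', sample '%s'",
                 beta[bad[1L, 1L], bad[1L, 2L]],
                 rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]]),
         call. = FALSE)
  }
  invisible(beta)
}

#' Read a probe-by-sample matrix
#'
#' Reads a delimited text matrix (first column probe IDs, header row sample
#' IDs).  Tab- or comma-delimited is auto-detected from the file extension.
#' `"NA"` (case-insensitive) and empty cells load as missing values.
#'
#' @param path file path.
#' @param kind one of `"beta"`, `"detection_p"` (both range-checked to
#'   \eqn{[0,1]}) or `"expression"` (log2 scale, unrestricted range).
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("beta", "detection_p", "expression")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus >=1 sample column", call. = FALSE)
  probes <- trimws(df[[1L]])
  samples <- colnames(df)[-1L]
  .check_unique(probes, "probe ID")
  .check_unique(samples, "sample ID")
  vals <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
                 dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    vals[, j] <- .parse_numeric_cells(df[[j + 1L]], kind,
                                      probe = probes,
                                      sample = rep(samples[j], length(probes)))
  }
  if (kind %in% c("beta", "detection_p")) validate_beta_matrix(vals)
  vals
}

#' Write a probe-by-sample matrix as TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path; missing values are written as `NA`.
#' @param id_col header for the first (probe ID) column.
#' @export
write_matrix <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(mat[, 0, drop = FALSE], check.names = FALSE)
  df[[id_col]] <- rownames(mat)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.canon_cpg <- function(x) {
  x <- trimws(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("", NA)] <- "OpenSea"
  out[grepl("shore$", x, ignore.case = TRUE)] <- "Shore"
  out[grepl("shelf$", x, ignore.case = TRUE)] <- "Shelf"
  out[grepl("^island$", x, ignore.case = TRUE)] <- "Island"
  out[grepl("^open ?sea$", x, ignore.case = TRUE)] <- "OpenSea"
  bad <- which(is.na(out))
  if (length(bad) > 0L)
    stop(sprintf("unknown CpG-island relation '%s'", x[bad[1L]]), call. = FALSE)
  out
}

#' Functional-group vocabulary for probe-gene associations
#' @export
FUNCTIONAL_GROUPS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                       "3'UTR", "intergenic")

#' CpG-island relation vocabulary
#' @export
CPG_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")

#' Read a probe annotation manifest
#'
#' Parses a 450K-manifest-style delimited table into a `probe_annotation`
#' object: one per-probe record (chromosome, position, CpG-island relation,
#' Infinium design type, SNP distance) plus a long table of per-gene
#' associations.  Manifest conventions are normalized on read: an optional
#' `chr` prefix is stripped from chromosome labels, `N_Shore`/`S_Shore`
#' collapse to `Shore` (likewise shelves), and an empty island relation means
#' `OpenSea`.  Multi-gene fields (`;`-separated) are split into one
#' association per gene; a probe with no gene is associated to the
#' `intergenic` functional group.
#'
#' @param path manifest path (TSV, or CSV by extension).
#' @param col_map named character vector mapping the canonical column names
#'   `probe_id, chr, pos, gene, gene_group, cpg_relation, design_type,
#'   snp_distance` to the names actually present in the file.
#' @return object of class `probe_annotation`: a list with `probes`
#'   (one row per probe) and `genes` (probe_id, gene, functional_group).
#' @export
read_annotation <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE)
  canon <- c("probe_id", "chr", "pos", "gene", "gene_group",
             "cpg_relation", "design_type", "snp_distance")
  map <- stats::setNames(canon, canon)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  required <- setdiff(canon, "snp_distance")
  missing_cols <- required[!map[required] %in% colnames(df)]
  if (length(missing_cols) > 0L)
    stop(sprintf("annotation is missing required column '%s'", map[missing_cols[1L]]),
         call. = FALSE)
  probe_id <- trimws(df[[map["probe_id"]]])
  .check_unique(probe_id, "annotation probe ID")
  chr <- sub("^chr", "", trimws(df[[map["chr"]]]), ignore.case = TRUE)
  pos <- .parse_numeric_cells(df[[map["pos"]]], "position", probe_id, chr)
  if (any(!is.na(pos) & pos < 1))
    stop("genomic positions must be >= 1 (1-based coordinates)", call. = FALSE)
  design <- trimws(df[[map["design_type"]]])
  if (!all(design %in% c("I", "II")))
    stop(sprintf("unknown Infinium design type '%s'",
                 design[which(!design %in% c("I", "II"))[1L]]), call. = FALSE)
  snp <- if (map["snp_distance"] %in% colnames(df)) {
    .parse_numeric_cells(df[[map["snp_distance"]]], "snp_distance", probe_id, chr)
  } else rep(NA_real_, length(probe_id))

  probes <- data.frame(
    probe_id = probe_id, chromosome = chr, position = pos,
    cpg_relation = .canon_cpg(df[[map["cpg_relation"]]]),
    design_type = design, snp_distance = snp,
    stringsAsFactors = FALSE)

  gene_field <- trimws(df[[map["gene"]]])
  group_field <- trimws(df[[map["gene_group"]]])
  assoc <- lapply(seq_along(probe_id), function(i) {
    genes <- strsplit(gene_field[i], ";", fixed = TRUE)[[1L]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      return(data.frame(probe_id = probe_id[i], gene = NA_character_,
                        functional_group = "intergenic", stringsAsFactors = FALSE))
    }
    groups <- strsplit(group_field[i], ";", fixed = TRUE)[[1L]]
    groups <- groups[nzchar(groups)]
    if (length(groups) == 1L) groups <- rep(groups, length(genes))
    if (length(groups) != length(genes))
      stop(sprintf("probe '%s': %d genes but %d gene groups", probe_id[i],
                   length(genes), length(groups)), call. = FALSE)
    data.frame(probe_id = probe_id[i], gene = genes, functional_group = groups,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, assoc)
  bad <- which(!genes$functional_group %in% FUNCTIONAL_GROUPS)
  if (length(bad) > 0L)
    stop(sprintf("unknown functional group '%s' (probe '%s')",
                 genes$functional_group[bad[1L]], genes$probe_id[bad[1L]]),
         call. = FALSE)
  structure(list(probes = probes, genes = genes), class = "probe_annotation")
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation: %d probes, %d gene associations\n",
              nrow(x$probes), nrow(x$genes)))
  invisible(x)
}

#' Build a probe_annotation from in-memory tables
#'
#' @param probes data.frame with columns probe_id, chromosome, position,
#'   cpg_relation, design_type, snp_distance.
#' @param genes data.frame with columns probe_id, gene, functional_group.
#' @return `probe_annotation` object.
#' @export
probe_annotation <- function(probes, genes) {
  stopifnot(all(c("probe_id", "chromosome", "position", "cpg_relation",
                  "design_type") %in% colnames(probes)),
            all(c("probe_id", "gene", "functional_group") %in% colnames(genes)))
  if (!"snp_distance" %in% colnames(probes)) probes$snp_distance <- NA_real_
  .check_unique(probes$probe_id, "annotation probe ID")
  stopifnot(all(probes$cpg_relation %in% CPG_RELATIONS),
            all(probes$design_type %in% c("I", "II")),
            all(genes$functional_group %in% FUNCTIONAL_GROUPS))
  structure(list(probes = as.data.frame(probes), genes = as.data.frame(genes)),
            class = "probe_annotation")
}

#' Read a sample sheet
#'
#' CSV (or TSV) with columns `sample_id`, `group` (`tumor`/`normal`) and an
#' optional `batch` label.
#'
#' @param path file path.
#' @return data.frame with columns sample_id, group, batch.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c("sample_id", "group"))
    if (!col %in% colnames(df))
      stop(sprintf("sample sheet is missing column '%s'", col), call. = FALSE)
  sheet <- data.frame(sample_id = trimws(df$sample_id),
                      group = trimws(df$group),
                      batch = if ("batch" %in% colnames(df)) trimws(df$batch)
                              else NA_character_,
                      stringsAsFactors = FALSE)
  .check_unique(sheet$sample_id, "sample ID")
  bad <- which(!sheet$group %in% c("tumor", "normal"))
  if (length(bad) > 0L)
    stop(sprintf("unknown group label '%s' (sample '%s')",
                 sheet$group[bad[1L]], sheet$sample_id[bad[1L]]), call. = FALSE)
  sheet
}

#' Read chromosome lengths
#'
#' Two-column delimited file: chromosome label, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of lengths, names are chromosome labels
#'   (with any `chr` prefix stripped).
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  chr <- sub("^chr", "", trimws(df[[1L]]), ignore.case = TRUE)
  len <- .parse_numeric_cells(df[[2L]], "chromosome length", chr, chr)
  if (any(is.na(len) | len <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  stats::setNames(len, chr)
}

#' Write a result-record table as TSV
#'
#' Writes DML or correlation records (any data.frame) as tab-delimited text
#' with one header row.  Numeric fields keep full precision so that
#' write-then-read round-trips exactly (to floating-point printing
#' precision); read back with [read_records()].
#'
#' @param records data.frame (possibly zero rows).
#' @param path output path.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  df <- records
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df[[j]][is.na(records[[j]])] <- "NA"
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result-record table written by [write_records()]
#'
#' @param path file path.
#' @return data.frame; columns that parse fully as numeric or logical are
#'   converted, the rest stay character.
#' @export
read_records <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    x <- df[[j]]
    miss <- toupper(trimws(x)) == "NA" | trimws(x) == ""
    if (all(x[!miss] %in% c("TRUE", "FALSE"))) {
      v <- as.logical(x); v[miss] <- NA; df[[j]] <- v; next
    }
    num <- suppressWarnings(as.numeric(x))
    if (!any(is.na(num[!miss]))) {
      num[miss] <- NA_real_; df[[j]] <- num
    } else {
      x[miss] <- NA_character_; df[[j]] <- x
    }
  }
  df
}

# Split a sample sheet into tumor / normal ID vectors, checking the matrix
# actually contains them.
.split_groups <- function(mat, sheet, min_per_group = 1L) {
  tum <- sheet$sample_id[sheet$group == "tumor"]
  nor <- sheet$sample_id[sheet$group == "normal"]
  tum <- tum[tum %in% colnames(mat)]
  nor <- nor[nor %in% colnames(mat)]
  if (length(tum) < min_per_group || length(nor) < min_per_group)
    stop(sprintf("need >= %d samples per group present in the matrix", min_per_group),
         call. = FALSE)
  list(tumor = tum, normal = nor)
}
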