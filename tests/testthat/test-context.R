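# Shared small annotation: 6 probes over two chromosomes with known
# contexts and gene associations.
ctx_ann <- function() {
  probe_annotation(
    probes = data.frame(
      probe_id = sprintf("p%d", 1:6),
      chromosome = c("1", "1", "1", "2", "2", "2"),
      position = c(10, 20, 30, 10, 20, 30) * 1e6,
      cpg_relation = c("Island", "Shore", "Shelf", "OpenSea", "Island", "Island"),
      design_type = "I", snp_distance = NA_real_),
    genes = data.frame(
      probe_id = c("p1", "p2", "p3", "p4", "p4", "p5", "p6"),
      gene = c("G1", "G2", "G3", "G4a", "G4b", "G5", NA),
      functional_group = c("TSS200", "Body", "Body", "Body", "Body",
                           "5'UTR", "intergenic")))
}

ctx_dml <- function() {
  data.frame(probe_id = sprintf("p%d", 1:6),
             direction = c("hyper", "hyper", "hypo", "hypo", "hypo", "hyper"),
             is_dml = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
}

test_that("chromosome frequencies count directions and normalize to length", {
  lengths <- c("1" = 1e8, "2" = 2e8)
  cf <- chromosome_frequency(ctx_dml(), ctx_ann(), lengths, scale = 1e8)
  expect_identical(cf$n_hyper, c(2L, 0L))
  expect_identical(cf$n_hypo, c(1L, 2L))
  expect_identical(cf$n_total, cf$n_hyper + cf$n_hypo)
  # 1 DML on a 1e8 bp chromosome at scale 1e8 -> frequency 1 per unit
  expect_equal(cf$freq_total, c(3, 1))

  # zero-DML chromosome still emitted
  lengths3 <- c(lengths, "3" = 5e7)
  cf3 <- chromosome_frequency(ctx_dml(), ctx_ann(), lengths3)
  expect_identical(cf3$n_total[3], 0L)

  # invariance to common rescaling of lengths and scale
  cf_scaled <- chromosome_frequency(ctx_dml(), ctx_ann(), lengths * 10,
                                    scale = 1e8 * 10)
  expect_equal(cf_scaled$freq_total, cf$freq_total)

  # unannotated DML excluded with a warning
  dml_extra <- rbind(ctx_dml(),
                     data.frame(probe_id = "ghost", direction = "hyper",
                                is_dml = TRUE))
  expect_warning(chromosome_frequency(dml_extra, ctx_ann(), lengths),
                 "missing from annotation")
})

test_that("functional distribution counts one contribution per distinct group", {
  fd <- functional_distribution(ctx_dml(), ctx_ann())
  expect_identical(fd$category, FUNCTIONAL_GROUPS)
  # p4 has two gene associations, both Body: counted once
  expect_identical(fd$n_all[fd$category == "Body"], 3L)
  expect_identical(fd$n_all[fd$category == "TSS200"], 1L)
  expect_identical(fd$n_hyper[fd$category == "TSS200"], 1L)
  expect_equal(sum(fd$pct_all), 100)
  expect_equal(sum(fd$pct_hyper), 100)
  expect_equal(sum(fd$pct_hypo), 100)
  # hand tally: all DML = {TSS200, Body, Body, Body, 5'UTR} -> Body 60%
  expect_equal(fd$pct_all[fd$category == "Body"], 60)

  # single-category degenerate case
  allbody <- probe_annotation(
    probes = ctx_ann()$probes,
    genes = data.frame(probe_id = sprintf("p%d", 1:6),
                       gene = sprintf("G%d", 1:6), functional_group = "Body"))
  fd2 <- functional_distribution(ctx_dml(), allbody)
  expect_equal(fd2$pct_all[fd2$category == "Body"], 100)
})

test_that("CpG context distribution is exhaustive and exclusive over DML", {
  cd <- cpg_context_distribution(ctx_dml(), ctx_ann())
  expect_identical(cd$category, CPG_RELATIONS)
  # 5 DML split Island 2 / Shore 1 / Shelf 1 / OpenSea 1
  expect_identical(cd$n_all, c(2L, 1L, 1L, 1L))
  expect_equal(cd$pct_all, c(40, 20, 20, 20))
  expect_identical(sum(cd$n_all), 5L)  # each DML in exactly one category
  expect_identical(cd$n_hyper + cd$n_hypo, cd$n_all)

  # planted-proportion recovery: every probe its own category mix
  set.seed(6)
  n <- 400
  rel <- sample(rep(CPG_RELATIONS, times = c(200, 120, 60, 20)))
  ann <- probe_annotation(
    probes = data.frame(probe_id = sprintf("q%d", 1:n), chromosome = "1",
                        position = seq_len(n), cpg_relation = rel,
                        design_type = "I", snp_distance = NA_real_),
    genes = data.frame(probe_id = "q1", gene = "G", functional_group = "Body"))
  dml <- data.frame(probe_id = sprintf("q%d", 1:n), direction = "hyper",
                    is_dml = TRUE)
  cd2 <- cpg_context_distribution(dml, ann)
  expect_equal(cd2$pct_all, c(50, 30, 15, 5))
})

test_that("complete-linkage clustering matches hand linkage and recovers groups", {
  # duplicated sample pair merges first at height 0
  b <- toy_beta(matrix(c(0.2, 0.2, 0.8), 1, 3), samples = c("a", "b", "c"))
  cl <- cluster_samples(b)
  expect_equal(cl$hclust$height[1], 0)
  expect_identical(sort(unname(cl$assignment[c("a", "b")])), c(1L, 1L))

  # 3 samples, pairwise distances 0.1, 0.2, 0.3: closest pair merges first,
  # final complete-linkage height is the largest distance
  b2 <- toy_beta(matrix(c(0.5, 0.6, 0.3), 1, 3), samples = c("a", "b", "c"))
  cl2 <- cluster_samples(b2)
  expect_equal(cl2$hclust$height, c(0.1, 0.3))

  # permutation equivariance of the assignment
  set.seed(8)
  m <- toy_beta(matrix(runif(60), 10, 6))
  perm <- sample(6)
  cl_a <- cluster_samples(m)
  cl_b <- cluster_samples(m[, perm])
  tab <- table(cl_a$assignment[colnames(m)[perm]], cl_b$assignment)
  expect_true(all(rowSums(tab > 0) == 1))  # same partition up to label swap

  expect_error(cluster_samples(m[, 1:2]), ">= 3 samples")

  # planted two-group structure is recovered exactly (ARI = 1)
  ds <- generate_dataset(small_config(seed = 3))
  pre <- preprocess(ds$beta, ds$detp, ds$ann)
  truth_probes <- intersect(ds$truth$dml$probe_id, rownames(pre$beta))
  cl3 <- cluster_samples(pre$beta[truth_probes, ])
  grp <- ds$sheet$group[match(names(cl3$assignment), ds$sheet$sample_id)]
  expect_equal(mclust::adjustedRandIndex(cl3$assignment, grp), 1)
})
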