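test_that("detection filter removes probes at the >= fraction boundary", {
  set.seed(1)
  beta <- toy_beta(matrix(runif(3 * 8), 3, 8))
  detp <- toy_beta(matrix(0.001, 3, 8))
  detp[1, 1:2] <- 0.2   # fails in 2/8 = 0.25 -> removed (boundary)
  detp[2, 1] <- 0.2     # fails in 1/8 -> retained
  res <- filter_detection(beta, detp)
  expect_identical(rownames(res$beta), c("p2", "p3"))
  expect_identical(res$report$removed, 1L)
  expect_identical(res$report$removed + res$report$retained, res$report$input)

  # all detection p below threshold: nothing removed
  res2 <- filter_detection(beta, toy_beta(matrix(0.01, 3, 8)))
  expect_identical(nrow(res2$beta), 3L)

  expect_error(filter_detection(beta, detp[, 1:4]), "share dimensions")
})

test_that("annotation filter drops sex chromosomes and SNP-proximal probes", {
  beta <- toy_beta(matrix(0.5, 5, 4),
                   probes = c("pX", "pSNP10", "pSNP11", "pAuto", "pMissing"))
  ann <- probe_annotation(
    probes = data.frame(
      probe_id = c("pX", "pSNP10", "pSNP11", "pAuto"),
      chromosome = c("X", "3", "3", "5"),
      position = c(1e6, 2e6, 3e6, 4e6),
      cpg_relation = "Island", design_type = "I",
      snp_distance = c(NA, 10, 11, NA)),
    genes = data.frame(probe_id = "pAuto", gene = "G1",
                       functional_group = "Body"))
  res <- filter_annotation(beta, ann, snp_bp = 10)
  expect_identical(rownames(res$beta), c("pSNP11", "pAuto"))
  expect_identical(res$report$removed_sex, 1L)
  expect_identical(res$report$removed_snp, 1L)
  expect_identical(res$report$removed_unannotated, 1L)
})

test_that("detection and annotation filters commute on the retained set", {
  set.seed(7)
  ds <- generate_dataset(small_config(seed = 7))
  a <- filter_annotation(filter_detection(ds$beta, ds$detp)$beta, ds$ann)$beta
  b <- filter_detection(ds$beta[rownames(filter_annotation(ds$beta, ds$ann)$beta), ],
                        ds$detp[rownames(filter_annotation(ds$beta, ds$ann)$beta), ])$beta
  expect_identical(sort(rownames(a)), sort(rownames(b)))
})

test_that("probe-type scaling is the identity on matched distributions and preserves ranks", {
  # all probes type I: untouched
  beta <- toy_beta(matrix(runif(20), 10, 2))
  ann1 <- probe_annotation(
    probes = data.frame(probe_id = rownames(beta), chromosome = "1",
                        position = seq_len(10), cpg_relation = "Island",
                        design_type = "I", snp_distance = NA_real_),
    genes = data.frame(probe_id = "p1", gene = "G", functional_group = "Body"))
  expect_identical(scale_design_types(beta, ann1), beta)

  # type II identical in distribution to type I -> output ~ input
  set.seed(3)
  vals <- sort(runif(500))
  beta2 <- toy_beta(matrix(c(vals, vals), ncol = 1), probes = sprintf("q%d", 1:1000),
                    samples = "s1")
  ann2 <- probe_annotation(
    probes = data.frame(probe_id = rownames(beta2), chromosome = "1",
                        position = seq_len(1000), cpg_relation = "OpenSea",
                        design_type = rep(c("I", "II"), each = 500),
                        snp_distance = NA_real_),
    genes = data.frame(probe_id = "q1", gene = "G", functional_group = "Body"))
  scaled <- scale_design_types(beta2, ann2)
  expect_lt(max(abs(scaled - beta2)), 1e-6)

  # monotonicity: within-sample ranking of type-II probes preserved
  set.seed(4)
  beta3 <- toy_beta(matrix(runif(1000), ncol = 1),
                    probes = rownames(beta2), samples = "s1")
  scaled3 <- scale_design_types(beta3, ann2)
  ii <- 501:1000
  expect_identical(order(scaled3[ii, 1]), order(beta3[ii, 1]))
  expect_true(all(scaled3 >= 0 & scaled3 <= 1))
})

test_that("quantile normalization matches the rank-mean oracle and is idempotent", {
  # hand-computed oracle: columns (0.1,0.2,0.3) and (0.3,0.4,0.5)
  b <- toy_beta(cbind(c(0.1, 0.2, 0.3), c(0.3, 0.4, 0.5)))
  qn <- quantile_normalize(b)
  expect_equal(unname(qn[, 1]), c(0.2, 0.3, 0.4))
  expect_equal(unname(qn[, 2]), c(0.2, 0.3, 0.4))

  # identical columns unchanged
  b2 <- toy_beta(cbind(c(0.5, 0.1, 0.9), c(0.5, 0.1, 0.9)))
  expect_equal(quantile_normalize(b2), b2)

  # row permutation equivariance
  set.seed(5)
  m <- toy_beta(matrix(runif(40), 10, 4))
  perm <- sample(10)
  expect_equal(quantile_normalize(m[perm, ]), quantile_normalize(m)[perm, ])

  # idempotence
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)

  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("logit transform hits its closed forms, clamps, and is antisymmetric", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)              # log2(4)
  expect_equal(beta_to_m(0), log2(0.001 / 0.999))
  expect_equal(beta_to_m(1), -log2(0.001 / 0.999))
  expect_error(beta_to_m(0.5, epsilon = 0.6), "epsilon")
  expect_error(beta_to_m(0.5, epsilon = 0), "epsilon")

  # antisymmetry and strict monotonicity on a grid
  g <- seq(0.001, 0.999, by = 0.001)
  expect_equal(beta_to_m(g), -beta_to_m(1 - g))
  expect_true(all(diff(beta_to_m(g)) > 0))

  # missing stays missing; inverse recovers clamped values
  expect_true(is.na(beta_to_m(NA)))
  expect_equal(m_to_beta(beta_to_m(g)), g, tolerance = 1e-12)
})

test_that("full preprocessing produces finite M-values and a consistent report", {
  ds <- generate_dataset(small_config(seed = 2))
  pre <- preprocess(ds$beta, ds$detp, ds$ann)
  expect_true(all(is.finite(pre$mvals[!is.na(pre$mvals)])))
  expect_true(all(pre$report$removed + pre$report$retained == pre$report$input))
  expect_identical(pre$report$retained[nrow(pre$report)], nrow(pre$beta))
  expect_true(all(pre$beta >= 0 & pre$beta <= 1, na.rm = TRUE))
})
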