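test_that("reference profile is the pairwise-complete normal mean", {
  sheet <- toy_sheet(c("t1"), c("n1", "n2", "n3"))
  b <- toy_beta(rbind(c(0.9, 0.4, 0.6, NA),
                      c(0.9, 0.3, NA, NA),
                      c(0.9, 0.2, NA, 0.4),
                      c(0.9, NA, NA, NA)),
                samples = c("t1", "n1", "n2", "n3"))
  mu <- reference_profile(b, sheet)
  expect_equal(unname(mu[c("p1", "p2", "p3")]), c(0.5, 0.3, 0.3))
  expect_false("p4" %in% names(mu))  # all-normal-missing probe omitted
})

test_that("binary discretization labels by the sign of beta minus mu", {
  sheet <- toy_sheet(c("t1", "t2", "t3"), c("n1", "n2"))
  b <- toy_beta(rbind(c(0.7, 0.3, 0.5, 0.5, 0.5),
                      c(0.9, NA, 0.1, 0.4, 0.6)),
                samples = sheet$sample_id)
  mu <- reference_profile(b, sheet)
  lab <- binary_discretize(b, mu, sheet)
  expect_identical(unname(lab["p1", ]), c("M", "U", "excluded"))  # tie excluded
  expect_identical(unname(lab["p2", ]), c("M", "excluded", "U"))
  expect_identical(attr(lab, "mode"), "binary")

  # probe absent from the reference: all labels excluded
  mu2 <- mu[setdiff(names(mu), "p2")]
  lab2 <- binary_discretize(b, mu2, sheet)
  expect_true(all(lab2["p2", ] == "excluded"))
})

test_that("ternary discretization opens a neutral band and converges to binary", {
  sheet <- toy_sheet(c("t1", "t2", "t3"), c("n1", "n2"))
  b <- toy_beta(rbind(c(0.75, 0.55, 0.3, 0.5, 0.5)),
                samples = sheet$sample_id)
  mu <- reference_profile(b, sheet)
  lab <- ternary_discretize(b, mu, sheet, threshold = 0.1)
  expect_identical(unname(lab["p1", ]), c("M", "neutral", "U"))
  expect_error(ternary_discretize(b, mu, sheet, threshold = 0), "> 0")
  expect_error(ternary_discretize(b, mu, sheet, threshold = -1), "> 0")

  # t -> 0 limit reproduces binary labels wherever beta != mu
  set.seed(10)
  sheet2 <- toy_sheet(sprintf("t%d", 1:6), sprintf("n%d", 1:3))
  bb <- toy_beta(matrix(runif(90), 10, 9), samples = sheet2$sample_id)
  mu2 <- reference_profile(bb, sheet2)
  tern <- ternary_discretize(bb, mu2, sheet2, threshold = 1e-9)
  bin <- binary_discretize(bb, mu2, sheet2)
  expect_identical(tern[bin != "excluded"], bin[bin != "excluded"])
})

test_that("ternary labels are consistent with binary and conserve samples", {
  set.seed(12)
  sheet <- toy_sheet(sprintf("t%d", 1:8), sprintf("n%d", 1:4))
  for (rep in 1:5) {
    b <- toy_beta(matrix(runif(240), 20, 12), samples = sheet$sample_id)
    b[sample(length(b), 10)] <- NA
    mu <- reference_profile(b, sheet)
    t <- runif(1, 0.01, 0.3)
    tern <- ternary_discretize(b, mu, sheet, threshold = t)
    bin <- binary_discretize(b, mu, sheet)
    # every ternary M (resp. U) is a binary M (resp. U)
    expect_true(all(bin[tern == "M"] == "M"))
    expect_true(all(bin[tern == "U"] == "U"))
    # label conservation per probe: all tumor samples accounted for
    counts <- apply(tern, 1L, function(r) sum(table(factor(
      r, levels = c("M", "U", "neutral", "excluded")))))
    expect_true(all(counts == 8))
  }
})

test_that("probe pairing is the gene-symbol cross-join", {
  ann <- probe_annotation(
    probes = data.frame(probe_id = sprintf("m%d", 1:5), chromosome = "1",
                        position = 1:5, cpg_relation = "Island",
                        design_type = "I", snp_distance = NA_real_),
    genes = data.frame(
      probe_id = c("m1", "m2", "m2", "m3", "m4", "m5"),
      gene = c("GENE1", "GENE1", "GENE2", "GENE3", NA, "GENE9"),
      functional_group = c("Body", "TSS200", "Body", "Body", "intergenic",
                           "Body")))
  expr_map <- data.frame(expr_probe_id = c("e1", "e2", "e3", "e4"),
                         gene = c("GENE1", "GENE1", "GENE2", "GENE4"))
  pairs <- pair_probes(ann, expr_map)
  # hand cross-join: GENE1 {m1,m2}x{e1,e2}, GENE2 {m2}x{e3}; GENE3/4/9 unmatched
  expect_identical(nrow(pairs), 5L)
  expect_identical(sum(pairs$meth_probe_id == "m1"), 2L)
  expect_identical(pairs$expr_probe_id[pairs$gene == "GENE2"], "e3")
  expect_identical(nrow(pair_probes(ann,
    data.frame(expr_probe_id = "e9", gene = "NOPE"))), 0L)
})

test_that("Welch test matches closed forms, t.test, and handles degeneracy", {
  w <- welch_test(c(1, 2), c(3, 4))
  expect_equal(w$t_stat, -2.8284271, tolerance = 1e-6)
  expect_equal(w$df, 2)
  # identical groups: t = 0, p = 1
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))[c("t_stat", "p_value")],
               list(t_stat = 0, p_value = 1))
  # antisymmetry
  set.seed(13)
  x <- rnorm(6); y <- rnorm(5, 1)
  expect_equal(welch_test(x, y)$t_stat, -welch_test(y, x)$t_stat)
  expect_equal(welch_test(x, y)$p_value, welch_test(y, x)$p_value)
  # cross-check against the standard implementation on random inputs
  for (rep in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), sd = 2)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    got <- welch_test(a, b)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # zero-variance branches
  expect_equal(welch_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_warning(w0 <- welch_test(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(w0$p_value, 0)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("Welch ordering agrees with a permutation-test oracle", {
  set.seed(14)
  agree <- 0L
  n_inst <- 100L
  for (i in seq_len(n_inst)) {
    x1 <- rnorm(5, runif(1, 0, 2)); y1 <- rnorm(5)
    x2 <- rnorm(5, runif(1, 0, 2)); y2 <- rnorm(5)
    w1 <- welch_test(x1, y1)$p_value; w2 <- welch_test(x2, y2)$p_value
    p1 <- perm_meandiff_p(x1, y1); p2 <- perm_meandiff_p(x2, y2)
    if (sign(w1 - w2) == sign(p1 - p2) || (w1 == w2 && p1 == p2))
      agree <- agree + 1L
  }
  expect_gte(agree, 95L)
})

test_that("direction is set by which discretization group expresses more", {
  expect_identical(direction_of(list(mean_expr_M = 5, mean_expr_U = 8)), -1)
  expect_identical(direction_of(list(mean_expr_M = 8, mean_expr_U = 5)), 1)
  expect_error(direction_of(list(mean_expr_M = 5, mean_expr_U = 5)),
               "no correlation direction")
})

test_that("correlate skips small groups, finds planted pairs, stays null-quiet", {
  sheet <- toy_sheet(sprintf("t%02d", 1:14), sprintf("n%d", 1:2))
  tumors <- sheet$sample_id[1:14]

  # hand-built labels: one probe with a 9/5 split, one with a 13/1 split
  lab <- matrix("M", nrow = 2, ncol = 14, dimnames = list(c("mA", "mB"), tumors))
  lab["mA", 10:14] <- "U"
  lab["mB", 14] <- "U"
  attr(lab, "mode") <- "binary"

  set.seed(15)
  expr <- matrix(rnorm(2 * 14, 8, 0.3), 2, 14,
                 dimnames = list(c("eA", "eB"), tumors))
  expr["eA", 1:9] <- expr["eA", 1:9] - 2   # M group expresses 2 log2 less
  pairs <- data.frame(meth_probe_id = c("mA", "mB"),
                      expr_probe_id = c("eA", "eB"), gene = c("GA", "GB"))
  res <- correlate(expr, lab, pairs)
  expect_identical(nrow(res), 1L)                 # mB/eB skipped (n_U = 1)
  expect_identical(attr(res, "n_skipped"), 1L)
  expect_true(res$significant)
  expect_identical(res$direction, -1L)
  expect_identical(c(res$n_M, res$n_U), c(9L, 5L))

  # all-null expression: across 20 seeds, mean significant count <= 0.5
  n_sig <- integer(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    nl <- matrix(sample(c("M", "U"), 300 * 14, TRUE), 300, 14,
                 dimnames = list(sprintf("m%03d", 1:300), tumors))
    attr(nl, "mode") <- "binary"
    ne <- matrix(rnorm(300 * 14, 8, 0.5), 300, 14,
                 dimnames = list(sprintf("e%03d", 1:300), tumors))
    np <- data.frame(meth_probe_id = rownames(nl), expr_probe_id = rownames(ne),
                     gene = rownames(nl))
    n_sig[s] <- sum(correlate(ne, nl, np)$significant)
  }
  expect_lte(mean(n_sig), 0.5)

  expect_warning(out <- correlate(expr, lab, pairs[0, ]), "empty pair list")
  expect_identical(nrow(out), 0L)
})
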