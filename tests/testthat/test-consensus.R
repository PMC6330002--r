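test_that("degenerate columns give the no-call sentinel", {
  cl <- genotype_call(make_column(character(), integer()))
  expect_equal(cl$genotype, c("N", "N"))
  expect_equal(cl$phred_conf, 0)
  expect_equal(cl$depth, 0L)
  # all-N column is equally uninformative but keeps its depth
  cl <- genotype_call(make_column(rep("N", 4), rep(30L, 4)))
  expect_equal(cl$genotype, c("N", "N"))
  expect_equal(cl$depth, 4L)
})

test_that("clean homozygous columns are called confidently", {
  col <- make_column(rep("A", 10), rep(30L, 10), 60L)
  cl <- genotype_call(col)
  expect_equal(cl$genotype, c("A", "A"))
  # the nearest competitor is always a heterozygote containing A, so the
  # confidence grows ~3 Phred per agreeing base; the enumeration oracle
  # puts 10 clean bases at ~24 Phred
  or <- oracle_genotype(col$base, col$qual, col$mapq)
  expect_equal(cl$raw_conf, or$raw_conf, tolerance = 1e-9)
  expect_gte(cl$raw_conf, 20)
  expect_equal(pessimistic_adjust(cl, col)$phred_conf, cl$raw_conf)
  # raw confidence is non-decreasing in the number of agreeing bases
  confs <- vapply(1:20, function(n)
    genotype_call(make_column(rep("A", n), rep(30L, n)))$raw_conf, numeric(1))
  expect_true(all(diff(confs) >= 0))
})

test_that("mixed columns match the brute-force enumeration oracle", {
  col <- make_column(c(rep("A", 6), rep("G", 4)), rep(20L, 10), 60L)
  cl <- genotype_call(col)
  or <- oracle_genotype(col$base, col$qual, col$mapq)
  expect_equal(sort(cl$genotype), sort(or$genotype))
  expect_equal(cl$raw_conf, or$raw_conf, tolerance = 1e-9)

  set.seed(101)
  for (i in 1:400) {
    col <- random_column()
    cl <- genotype_call(col)
    or <- oracle_genotype(col$base, col$qual, col$mapq)
    if (cl$genotype[1] == "N") { expect_equal(or$genotype, c("N", "N")); next }
    margin <- diff(sort(or$ll, decreasing = TRUE)[2:1])
    if (is.finite(margin) && margin > 1e-6) {
      # unambiguous argmax: must match exactly
      expect_identical(sort(cl$genotype), sort(or$genotype))
    } else {
      # numerically tied: the implementation's pick must be likelihood-
      # equivalent to the oracle's best
      expect_gte(oracle_ll_of(or, cl$genotype), max(or$ll) - 1e-9)
    }
    expect_equal(cl$raw_conf, or$raw_conf, tolerance = 1e-6)
  }
})

test_that("the caller is deterministic and symmetric under base relabeling", {
  # tie-free column: the likelihood argmax is unique, so relabeling the
  # alphabet must relabel the call identically
  col <- make_column(c("A", "A", "A", "C", "C", "G"),
                     c(30L, 25L, 20L, 35L, 18L, 12L), 60L)
  expect_identical(genotype_call(col), genotype_call(col))
  for (p in list(c(A = "T", C = "G", G = "A", T = "C"),
                 c(A = "C", C = "A", G = "T", T = "G"),
                 c(A = "G", C = "T", G = "C", T = "A"))) {
    perm <- c(p, "*" = "*", N = "N")
    col2 <- col; col2$base <- unname(perm[col$base])
    g1 <- genotype_call(col)$genotype
    g2 <- genotype_call(col2)$genotype
    expect_setequal(unname(perm[g1]), g2)
    expect_equal(genotype_call(col2)$raw_conf, genotype_call(col)$raw_conf,
                 tolerance = 1e-9)
  }
})

test_that("pessimistic adjustment subtracts mismatching evidence, floored at 0", {
  # zero mismatches: untouched
  col <- make_column(rep("C", 5), rep(35L, 5))
  cl <- genotype_call(col)
  expect_equal(pessimistic_adjust(cl, col)$phred_conf, cl$raw_conf)
  # one mismatching entry min(qual, mapq) = 5 costs exactly 5
  col <- make_column(c(rep("A", 20), "G"), c(rep(30L, 20), 5L), 60L)
  cl <- genotype_call(col)
  expect_equal(cl$genotype, c("A", "A"))
  adj <- pessimistic_adjust(cl, col)
  expect_gt(cl$raw_conf, 5)
  expect_equal(adj$phred_conf, cl$raw_conf - 5)
  # idempotent
  expect_equal(pessimistic_adjust(adj, col)$phred_conf, adj$phred_conf)
  # random columns: adjusted <= raw, equality iff no mismatches (N excluded)
  set.seed(202)
  for (i in 1:200) {
    col <- random_column()
    cl <- genotype_call(col)
    adj <- pessimistic_adjust(cl, col)
    expect_lte(adj$phred_conf, cl$raw_conf)
    pen <- oracle_penalty(col$base, col$qual, col$mapq, cl$genotype)
    expect_equal(adj$phred_conf, max(0, cl$raw_conf - pen))
  }
})

test_that("vectorised consensus equals the single-column path", {
  sim <- simulate_alignments(ref_len = 1200L, depth = 15, err_rate = 0.01,
                             var_density = 0.005, seed = 7L)
  pu <- build_pileup(sim$records)
  calls <- call_consensus(pu)
  cols <- pileup_columns(pu)
  set.seed(3)
  pick <- sample(names(cols), 40L)
  for (nm in pick) {
    cl <- pessimistic_adjust(genotype_call(cols[[nm]]), cols[[nm]])
    row <- calls[calls$pos == as.integer(nm), ]
    expect_identical(sort(c(row$g1, row$g2)), sort(cl$genotype))
    expect_equal(row$raw_conf, cl$raw_conf, tolerance = 1e-9)
    expect_equal(row$phred_conf, cl$phred_conf, tolerance = 1e-9)
  }
})

test_that("confidence thresholding is inclusive and monotone", {
  expect_false(is_confident(0, caller_params(conf_threshold = 30)))
  expect_true(is_confident(30, caller_params(conf_threshold = 30)))
  sim <- simulate_alignments(ref_len = 2000L, depth = 20, err_rate = 0.005,
                             seed = 19L)
  calls <- call_consensus(build_pileup(sim$records))
  n_conf <- vapply(c(0, 10, 20, 30, 40, 50, 60, 99),
                   function(th) sum(is_confident(calls$phred_conf,
                                                 caller_params(conf_threshold = th))),
                   numeric(1))
  expect_true(all(diff(n_conf) <= 0))
  # nothing clears an infinite bar
  expect_equal(sum(is_confident(calls$phred_conf,
                                caller_params(conf_threshold = Inf))), 0)
})
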