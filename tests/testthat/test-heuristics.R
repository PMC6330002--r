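test_that("concordant soft clips flag the shared site", {
  # no clips -> nothing
  pu <- build_pileup(make_reads(101L, "5M", "ACGTA", list(rep(30L, 5))))
  expect_equal(nrow(detect_softclip_concordance(pu)), 0L)
  # 5 of 10 spanning reads clip at reference position 150
  pos <- rep(121L, 10L)
  cig <- c(rep("30M20S", 5), rep("50M", 5))
  sq <- strrep("A", 50)
  pu <- build_pileup(make_reads(pos, cig, rep(sq, 10), rep(list(rep(30L, 50)), 10)))
  hp <- heuristic_params(clip_min_count = 3L, clip_min_fraction = 0.3, pad = 10L)
  iv <- detect_softclip_concordance(pu, hp)
  expect_equal(iv[, c("start", "end")], data.frame(start = 140L, end = 160L))
  expect_equal(iv$tag, "softclip")
  # a stricter count threshold silences it
  expect_equal(nrow(detect_softclip_concordance(
    pu, heuristic_params(clip_min_count = 6L))), 0L)
})

test_that("a simulated novel insertion is flagged at its breakpoint", {
  sim <- simulate_alignments(ref_len = 4000L, depth = 30, seed = 11L,
                             anomalies = list(insertion = list(pos = 2000L, len = 40L)))
  pu <- build_pileup(sim$records)
  iv <- detect_softclip_concordance(pu)
  bp <- sim$truth$anomalies$insertion$breakpoint
  expect_true(any(iv$start <= bp & bp < iv$end))
})

test_that("excessive depth is flagged where planted", {
  sim <- simulate_alignments(ref_len = 3000L, depth = 30, seed = 13L)
  calls <- call_consensus(build_pileup(sim$records))
  expect_equal(nrow(detect_excess_depth(calls, heuristic_params(depth_max = 100L))), 0L)
  sim2 <- simulate_alignments(ref_len = 3000L, depth = 30, seed = 13L,
                              anomalies = list(collapsed_repeat = list(start = 1000L, end = 1600L)))
  calls2 <- call_consensus(build_pileup(sim2$records))
  iv <- detect_excess_depth(calls2, heuristic_params(depth_max = 45L, pad = 0L))
  expect_gt(nrow(iv), 0L)
  # flagged region overlaps the duplicated tract
  expect_true(any(iv$start < 1600L & iv$end > 1000L))
  expect_true(all(iv$tag == "depth"))
})

test_that("low-MAPQ reads and loci are retained, with colocated keepers", {
  r <- make_reads(c(101L, 101L), c("5M", "5M"), c("ACGTA", "ACGTA"),
                  rep(list(rep(30L, 5)), 2), mapq = c(60L, 60L))
  pu <- build_pileup(r)
  res <- detect_low_mapq(pu, call_consensus(pu, mapq_low = 10L),
                         heuristic_params(mapq_low = 10L))
  expect_equal(nrow(res$intervals), 0L)
  expect_length(res$whole_read_ids, 0L)
  # one read below the bar gets whole-read retention
  r$mapq[2] <- 5L
  pu <- build_pileup(r)
  res <- detect_low_mapq(pu, call_consensus(pu, mapq_low = 10L),
                         heuristic_params(mapq_low = 10L, low_mapq_fraction = 0.9))
  expect_equal(res$whole_read_ids, 2L)

  sim <- simulate_alignments(ref_len = 4000L, depth = 25, seed = 17L,
                             anomalies = list(low_mapq = list(start = 1500L, end = 2500L,
                                                              frac = 0.4, mapq = 0L)))
  hp <- heuristic_params(mapq_low = 10L, low_mapq_fraction = 0.25,
                         keep_colocated_high_mapq = TRUE)
  pu <- build_pileup(sim$records)
  res <- detect_low_mapq(pu, call_consensus(pu, mapq_low = hp$mapq_low), hp)
  expect_true(any(res$intervals$start < 2500L & res$intervals$end > 1500L))
  kept_mapq <- sim$records$mapq[res$whole_read_ids]
  expect_true(any(kept_mapq == 0L))   # the misplaced reads themselves
  expect_true(any(kept_mapq == 60L))  # plus colocated high-MAPQ reads
  # without the colocation option the high-MAPQ reads are not retained
  hp2 <- heuristic_params(mapq_low = 10L, low_mapq_fraction = 0.25,
                          keep_colocated_high_mapq = FALSE)
  res2 <- detect_low_mapq(pu, call_consensus(pu, mapq_low = hp2$mapq_low), hp2)
  expect_true(all(sim$records$mapq[res2$whole_read_ids] == 0L))
})

test_that("more than two well-supported alleles flag the locus", {
  col_reads <- function(bases) {
    n <- length(bases)
    make_reads(rep(101L, n), rep("1M", n), bases, as.list(rep(30L, n)))
  }
  hp <- heuristic_params(pad = 0L)
  iv <- detect_excess_alleles(call_consensus(build_pileup(col_reads(rep("A", 10)))), hp)
  expect_equal(nrow(iv), 0L)
  iv <- detect_excess_alleles(call_consensus(build_pileup(col_reads(c(rep("A", 5), rep("C", 4))))), hp)
  expect_equal(nrow(iv), 0L)
  pu <- build_pileup(col_reads(c(rep("A", 5), rep("C", 4), rep("G", 3))))
  iv <- detect_excess_alleles(call_consensus(pu), hp)
  expect_equal(iv[, c("start", "end")], data.frame(start = 100L, end = 101L))
  # a lone error base is not an allele (support floor)
  pu <- build_pileup(col_reads(c(rep("A", 5), rep("C", 4), "G")))
  expect_equal(nrow(detect_excess_alleles(call_consensus(pu), hp)), 0L)
})

test_that("low-confidence calls are retained with context padding", {
  sim <- simulate_alignments(ref_len = 2000L, depth = 30, err_rate = 0,
                             var_density = 0, seed = 19L)
  calls <- call_consensus(build_pileup(sim$records))
  cp <- caller_params(conf_threshold = 30)
  hp <- heuristic_params(pad = 5L)
  iv <- detect_low_conf_calls(calls, cp, hp)
  # only the low-coverage edges of the window fail the bar
  interior <- iv$start < 1800L & iv$end > 200L
  expect_false(any(interior))
  # a single failing locus becomes one pad-widened interval around it
  fake <- calls_from_seq("AGTC", start = 500L)
  fake$phred_conf <- c(90, 12, 90, 90)
  iv <- detect_low_conf_calls(fake, cp, hp)
  expect_equal(iv[, c("start", "end")], data.frame(start = 496L, end = 507L))
  # a het SNP at 4x depth is too uncertain and lands in the mask
  sim4 <- simulate_alignments(ref_len = 2000L, depth = 4, err_rate = 0.005,
                              var_density = 0.002, het_fraction = 1, seed = 19L)
  hets <- subset(sim4$truth$variants, type == "SNP")
  calls4 <- call_consensus(build_pileup(sim4$records))
  iv4 <- detect_low_conf_calls(calls4, caller_params(conf_threshold = 60), hp)
  covered <- hets$pos0[calls4$depth[match(hets$pos0, calls4$pos)] >= 1L]
  expect_gt(length(covered), 0L)
  for (p in covered)
    expect_true(any(iv4$start <= p & p < iv4$end))
})

test_that("tandem repeat tracts match a quadratic brute-force scan", {
  hp0 <- heuristic_params(pad = 0L, str_unit_max = 4L, str_min_copies = 3L)
  # 2.25 copies of ACGT: not a tract
  expect_equal(nrow(detect_str(calls_from_seq("ACGTACGTA"), NULL, hp0)), 0L)
  # 6xA homopolymer: exactly the tract (positions 53..58)
  iv <- detect_str(calls_from_seq("GCTAAAAAAGCT", start = 50L), NULL, hp0)
  expect_equal(iv[, c("start", "end")], data.frame(start = 53L, end = 59L))
  # planted (AC)8 inside an otherwise repeat-free sequence
  set.seed(23)
  base <- qualcrunch:::scrub_str(sample(c("A", "C", "G", "T"), 300, TRUE))
  base[141:156] <- rep(c("A", "C"), 8)
  s <- paste(base, collapse = "")
  iv <- detect_str(calls_from_seq(s), NULL, hp0)
  paint <- oracle_paint(iv, 0L, 300L)
  expect_identical(paint, oracle_str_paint(base, 4L, 3L))
  expect_true(all(which(paint) >= 141 - 3 & which(paint) <= 156 + 3))
  # padding widens symmetrically
  hp10 <- heuristic_params(pad = 10L, str_min_copies = 3L)
  iv10 <- detect_str(calls_from_seq(s), NULL, hp10)
  expect_equal(iv10$start, iv$start - 10L)
  expect_equal(iv10$end, iv$end + 10L)
})

test_that("mask assembly merges intervals and tags like a paint oracle", {
  expect_equal(nrow(assemble_mask()$intervals), 0L)
  m <- assemble_mask(data.frame(start = 10L, end = 20L, tag = "softclip"),
                     data.frame(start = 15L, end = 30L, tag = "str"))
  expect_equal(m$intervals$start, 10L)
  expect_equal(m$intervals$end, 30L)
  expect_equal(m$intervals$tag, "softclip,str")
  # adjacent intervals merge too
  m <- assemble_mask(data.frame(start = c(0L, 10L), end = c(10L, 20L), tag = "depth"))
  expect_equal(nrow(m$intervals), 1L)

  set.seed(31)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    st <- sample(0:180, n, replace = TRUE)
    iv <- data.frame(start = st, end = st + sample(1:30, n, replace = TRUE),
                     tag = sample(c("depth", "str", "mapq"), n, replace = TRUE))
    m <- assemble_mask(iv)
    expect_identical(oracle_paint(m$intervals, 0L, 250L), oracle_paint(iv, 0L, 250L))
    # disjoint, sorted, tagged
    expect_true(all(diff(m$intervals$start) > 0))
    expect_true(all(utils::head(m$intervals$end, -1) < utils::tail(m$intervals$start, -1)))
    expect_true(all(nchar(m$intervals$tag) > 0))
    # idempotent and order-independent
    expect_identical(assemble_mask(m$intervals)$intervals, m$intervals)
    expect_identical(assemble_mask(iv[rev(seq_len(n)), ])$intervals, m$intervals)
  }
})

test_that("the mask grows monotonically as thresholds loosen", {
  sim <- simulate_alignments(ref_len = 4000L, depth = 30, err_rate = 0.005,
                             seed = 29L,
                             anomalies = list(insertion = list(pos = 1200L, len = 40L),
                                              collapsed_repeat = list(start = 2500L, end = 3000L)))
  run_mask <- function(hp) {
    pu <- build_pileup(sim$records)
    calls <- call_consensus(pu, mapq_low = hp$mapq_low)
    assemble_mask(detect_softclip_concordance(pu, hp),
                  detect_excess_depth(calls, hp),
                  detect_low_mapq(pu, calls, hp),
                  detect_excess_alleles(calls, hp))
  }
  tight <- run_mask(heuristic_params(depth_max = 80L, clip_min_count = 4L))
  loose <- run_mask(heuristic_params(depth_max = 40L, clip_min_count = 2L))
  pt <- oracle_paint(tight$intervals, 0L, 4000L)
  pl <- oracle_paint(loose$intervals, 0L, 4000L)
  expect_true(all(pl[pt]))   # loose mask is a superset
  expect_gt(sum(pl), sum(pt))
})

test_that("conf_threshold = Inf retains every covered locus", {
  sim <- simulate_alignments(ref_len = 1500L, depth = 10, seed = 41L)
  pu <- build_pileup(sim$records)
  cp <- caller_params(conf_threshold = Inf)
  calls <- call_consensus(pu, cp)
  iv <- detect_low_conf_calls(calls, cp, heuristic_params(pad = 0L))
  paint <- oracle_paint(iv, pu$span[1], pu$span[2])
  expect_identical(paint, diff(pu$offsets) > 0L)
})
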