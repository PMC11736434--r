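test_that("chi-squared matches the hand-computed table and an independent oracle", {
  tab <- matrix(c(30, 10, 10, 30), 2, dimnames = list(NULL, c("A", "B")))
  st <- apadyn:::chi2_stat(tab)
  expect_equal(st$chi2, 20.0, tolerance = 1e-12)
  expect_equal(st$df, 1L)
  expect_equal(pchisq(20, 1, lower.tail = FALSE), 7.744216e-06,
               tolerance = 1e-6)
  # perfectly homogeneous table
  st0 <- apadyn:::chi2_stat(matrix(10, 2, 2))
  expect_equal(st0$chi2, 0)

  # oracle: stats::chisq.test without continuity correction, random tables
  set.seed(101)
  for (i in 1:1000) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tb <- matrix(sample(0:50, nr * nc, replace = TRUE), nr, nc)
    if (any(colSums(tb) == 0) || sum(rowSums(tb) > 0) < 2) next
    st <- apadyn:::chi2_stat(tb)
    tb2 <- tb[rowSums(tb) > 0, , drop = FALSE]
    or <- suppressWarnings(stats::chisq.test(tb2, correct = FALSE))
    expect_equal(st$chi2, unname(or$statistic), tolerance = 1e-10)
    expect_equal(st$df, unname(or$parameter))
  }
})

test_that("BH adjustment matches the step-up definition and stats::p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(55)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- adjust_bh(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    # brute-force step-up: q_i = min over p_(j) >= p_i of m p_(j) / j
    m <- length(p)
    ps <- sort(p)
    brute <- vapply(p, function(pi) {
      js <- which(ps >= pi - 1e-15)
      min(1, min(m * ps[js] / js))
    }, numeric(1))
    expect_equal(q, brute)
  }
})

test_that("direction classification follows q and the index delta", {
  expect_equal(classify_direction(1e-4, 2.0), "shortening")
  expect_equal(classify_direction(1e-4, -2.0), "lengthening")
  expect_equal(classify_direction(0.2, 3.0), "none")
  expect_equal(classify_direction(c(0.01, 0.2), c(-1, -1)),
               c("lengthening", "none"))
})

test_that("pairwise differential is antisymmetric under label swap", {
  w <- tiny_world()
  units <- make_utr_units(w$groups, w$cm$counts)
  ab <- chi2_differential(units, c("C1", "C4"))
  ba <- chi2_differential(units, c("C4", "C1"))
  expect_equal(ab$p, ba$p)
  expect_equal(ab$chi2, ba$chi2)
  expect_equal(ab$delta, -ba$delta)
  swap <- c(shortening = "lengthening", lengthening = "shortening",
            none = "none")
  expect_equal(unname(swap[ab$direction]), ba$direction)
})

test_that("zero-total columns cause units to be skipped and tallied", {
  units <- list(
    ok = matrix(c(5L, 5L, 3L, 7L), 2, dimnames = list(NULL, c("A", "B"))),
    empty = matrix(c(5L, 5L, 0L, 0L), 2, dimnames = list(NULL, c("A", "B"))))
  d <- chi2_differential(units, c("A", "B"))
  expect_equal(d$unit_id, "ok")
  expect_equal(attr(d, "skipped"), "empty")
})

test_that("intron units test intronic vs summed 3'UTR counts", {
  pk <- data.table::data.table(
    peak_id = c("u1", "u2", "i1"), gene_id = "g1",
    region_class = c("utr3", "utr3", "intron"), chrom = "chr1",
    start = c(100L, 300L, 50L), end = c(110L, 310L, 60L),
    strand = "+", edge3 = c(109L, 309L, 59L))
  counts <- matrix(c(30L, 10L, 10L, 10L, 10L, 30L), ncol = 2,
                   dimnames = list(c("u1", "u2", "i1"), c("A", "B")))
  units <- make_intron_units(pk, counts)
  expect_equal(unname(units$i1["intron", ]), c(10L, 30L))
  expect_equal(unname(units$i1["utr3", ]), c(40L, 20L))
  d <- chi2_differential(units, c("A", "B"),
                         index_fun = function(v) ipui(v[1], v[2]))
  expect_equal(d$delta, ipui(30, 20) - ipui(10, 40))
})

test_that("distribution comparisons match their oracles", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_pui_distributions(c(x, x), rep(c("a", "b"), each = 5), "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(compare_pui_distributions(c(x, x), rep(c("a", "b"), each = 5),
                                         "ks")$statistic, 0)
  kw0 <- compare_pui_distributions(rep(x, 2), rep(c("a", "b"), each = 5),
                                   "kruskal")
  expect_equal(kw0$statistic, 0)
  # hand-ranked Kruskal-Wallis: groups {1,2,3},{4,5,6},{7,8,9} -> H = 7.2
  kw <- compare_pui_distributions(1:9, rep(c("a", "b", "c"), each = 3),
                                  "kruskal")
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  # errors on malformed groupings
  expect_error(compare_pui_distributions(1:4, c("a", "a", "b", "c"), "t"),
               "exactly two")
  expect_error(compare_pui_distributions(c(1, 2, 3), c("a", "a", "b"), "t"),
               ">= 2")
})

test_that("mutual dynamic set is exact set algebra with a Venn partition", {
  r <- mutual_dynamic_set(c("a", "b", "c"), c("b", "d"), c("c", "e"))
  expect_equal(r$mutual, c("b", "c"))
  expect_equal(sum(r$venn), length(unique(c("a", "b", "c", "d", "e"))))
  r0 <- mutual_dynamic_set("x", "y", "z")
  expect_equal(r0$mutual, character(0))
  # region sizes always partition the union
  set.seed(9)
  for (i in 1:20) {
    a <- sample(letters, 8); b <- sample(letters, 8); cc <- sample(letters, 8)
    rr <- mutual_dynamic_set(a, b, cc)
    expect_equal(sum(rr$venn), length(unique(c(a, b, cc))))
  }
})

test_that("planted shifts are recovered with controlled FDR", {
  cfg <- sim_config(n_genes = 30L, cells_per_cluster = 50L,
                    frac_shift_genes = 0.5, shift_delta = 0.4,
                    artifact_rate = 0, intron_pas_prob = 0, seed = 23L)
  ref <- generate_reference(cfg)
  tags <- simulate_tags(ref)
  pk <- call_peaks(tags, ref$annotation)
  cm <- build_count_matrices(pk, tags)
  kept <- filter_peaks(cm$peaks, cm$cpm, ref$genome, "utr3")$kept
  units <- make_utr_units(group_utr_peaks(kept), cm$counts)
  d <- chi2_differential(units, c("C1", "C4"), alpha = 0.05)
  shifted <- ref$truth$genes[shifted == TRUE, gene_id]
  calls <- d[direction == "shortening", unit_id]
  expect_gte(mean(shifted %in% calls), 0.8)
  fdr <- if (length(calls)) mean(!(calls %in% shifted)) else 0
  expect_lte(fdr, 0.075)
})

test_that("trend summary tracks the planted proximal ramp between adjacent clusters", {
  w <- tiny_world()
  bcs <- attr(w$tags, "barcodes")
  pc <- ppui_cell_matrix(w$groups, w$cm$cell_counts, bcs$barcode)
  mc <- summarize_cell_ppui(pc)
  units <- make_utr_units(w$groups, w$cm$counts)
  ts <- trend_summary(mc[bcs$barcode], bcs$cluster, w$cfg$cluster_ordering, units)
  expect_equal(nrow(ts), 3L)
  # ramp means rise along the ordering; more shortening than lengthening calls
  expect_true(all(ts$mean_b >= ts$mean_a))
  expect_true(sum(ts$n_shortening) > sum(ts$n_lengthening))
  expect_true(all(ts$n_shortening + ts$n_lengthening <= length(units)))
})
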