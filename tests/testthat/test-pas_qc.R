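# genome fixture: one chromosome of C with controllable plants
mk_genome <- function(len = 2000L, chrom = "chr1") {
  setNames(strrep("C", len), chrom)
}
plant <- function(genome, chrom, at, seq) {  # at: 0-based start
  substr(genome[[chrom]], at + 1L, at + nchar(seq)) <- seq
  genome
}
mk_peak <- function(edge3, strand = "+", id = "p1", gene = "g1",
                    region = "utr3", chrom = "chr1") {
  data.table::data.table(peak_id = id, gene_id = gene, region_class = region,
                         chrom = chrom, start = edge3 - 10L, end = edge3 + 1L,
                         strand = strand, edge3 = as.integer(edge3))
}
mk_cpm <- function(peak_ids, values) {
  matrix(values, nrow = length(peak_ids), ncol = length(values), byrow = TRUE,
         dimnames = list(peak_ids, paste0("cl", seq_along(values))))
}

test_that("internal-priming rule removes 3'UTR peaks with A8 in 10-140 nt downstream", {
  g <- plant(mk_genome(), "chr1", 520L, strrep("A", 8L))  # starts +20 from edge
  pk <- mk_peak(500L)
  fr <- filter_peaks(pk, mk_cpm("p1", c(50, 50)), g, "utr3")
  expect_equal(nrow(fr$kept), 0L)
  expect_equal(unname(fr$n_removed_by_rule["internal_priming"]), 1L)
  # run of 7 only, or run starting outside the window: retained
  g7 <- plant(mk_genome(), "chr1", 520L, strrep("A", 7L))
  expect_equal(nrow(filter_peaks(pk, mk_cpm("p1", c(50, 50)), g7, "utr3")$kept), 1L)
  gout <- plant(mk_genome(), "chr1", 645L, strrep("A", 8L))  # starts +145
  expect_equal(nrow(filter_peaks(pk, mk_cpm("p1", c(50, 50)), gout, "utr3")$kept), 1L)
})

test_that("A-run window is strand-aware and truncates at chromosome ends", {
  # minus strand: downstream = decreasing coordinates, sense A = reference T
  g <- plant(mk_genome(), "chr1", 472L, strrep("T", 8L))  # sense +20..+27 of edge 500
  pk <- mk_peak(500L, strand = "-")
  fr <- filter_peaks(pk, mk_cpm("p1", c(50, 50)), g, "utr3")
  expect_equal(nrow(fr$kept), 0L)
  # peak near the chromosome end: window truncation must not error
  pk2 <- mk_peak(1995L)
  expect_silent(fr2 <- filter_peaks(pk2, mk_cpm("p1", c(50, 50)), mk_genome(), "utr3"))
  expect_equal(nrow(fr2$kept), 1L)
})

test_that("CPM thresholds sit exactly at the stated boundaries", {
  g <- mk_genome()
  pk <- mk_peak(500L)
  expect_equal(nrow(filter_peaks(pk, mk_cpm("p1", c(4.5, 5.0)), g, "utr3")$kept), 0L)  # 9.5
  expect_equal(nrow(filter_peaks(pk, mk_cpm("p1", c(5.0, 5.0)), g, "utr3")$kept), 1L)  # 10.0
  # intron: < 5 in any cluster removes even when the total passes
  pki <- mk_peak(500L, region = "intron")
  expect_equal(nrow(filter_peaks(pki, mk_cpm("p1", c(4.9, 20)), g, "intron")$kept), 0L)
  expect_equal(nrow(filter_peaks(pki, mk_cpm("p1", c(5.0, 20)), g, "intron")$kept), 1L)
})

test_that("an intron peak violating two rules is counted once per rule", {
  g <- plant(mk_genome(), "chr1", 650L, strrep("A", 7L))  # +150, inside 1-200
  pki <- mk_peak(500L, region = "intron")
  fr <- filter_peaks(pki, mk_cpm("p1", c(4.9, 20)), g, "intron")
  expect_equal(nrow(fr$kept), 0L)
  expect_equal(unname(fr$n_removed_by_rule["low_cluster_cpm"]), 1L)
  expect_equal(unname(fr$n_removed_by_rule["internal_priming"]), 1L)
})

test_that("filtering is idempotent and order-insensitive", {
  w <- tiny_world()
  fr1 <- filter_peaks(w$cm$peaks, w$cm$cpm, w$ref$genome, "utr3")
  fr2 <- filter_peaks(fr1$kept, w$cm$cpm, w$ref$genome, "utr3")
  expect_equal(nrow(fr2$kept), nrow(fr1$kept))
  expect_true(all(fr2$n_removed_by_rule == 0L))
  shuf <- w$cm$peaks[sample(nrow(w$cm$peaks))]
  fr3 <- filter_peaks(shuf, w$cm$cpm, w$ref$genome, "utr3")
  expect_equal(sort(fr3$removed$peak_id), sort(fr1$removed$peak_id))
  expect_equal(fr3$n_removed_by_rule, fr1$n_removed_by_rule)
})

test_that("motif scan records end offsets on the sense strand", {
  g <- plant(mk_genome(), "chr1", 474L, "AATAAA")  # ends at 479 = edge - 21
  pk <- mk_peak(500L)
  mp <- scan_polya_signals(pk, g)
  expect_equal(mp$offsets[motif == "AATAAA", offset], -21L)
  expect_true(mp$flags$canonical)
  # no signal anywhere: flag is FALSE
  mp0 <- scan_polya_signals(pk, mk_genome())
  expect_false(mp0$flags$canonical)
  # minus strand plant
  gm <- plant(mk_genome(), "chr1", 521L, "TTTATT")  # sense AATAAA ending -21
  mpm <- scan_polya_signals(mk_peak(500L, strand = "-"), gm)
  expect_equal(mpm$offsets[motif == "AATAAA", offset], -21L)
})

test_that("canonical-signal fraction tracks the simulator's planting fraction", {
  cfg <- sim_config(n_genes = 40L, cells_per_cluster = 30L, signal_prob = 0.7,
                    jitter_sd = 0, artifact_rate = 0, seed = 13L)
  ref <- generate_reference(cfg)
  tags <- simulate_tags(ref)
  pk <- call_peaks(tags, ref$annotation)
  mp <- scan_polya_signals(pk[pk$region_class == "utr3"], ref$genome)
  expect_lt(abs(mean(mp$flags$canonical) - 0.7), 0.08)
})

test_that("KS comparison of signal densities behaves at the extremes", {
  x <- c(-90, -50, -10, 20, 60)
  expect_equal(compare_signal_density(x, x)$D, 0)
  expect_equal(compare_signal_density(x, x)$p.value, 1)
  r <- compare_signal_density(c(-90, -80, -70), c(50, 60, 70))
  expect_equal(r$D, 1)
  # offsets beyond +/- window are dropped; empty samples error
  expect_error(compare_signal_density(c(150, 200), x), "empty")
})

test_that("benchmarking against known sites measures nearest distances", {
  pk <- mk_peak(1000L)
  known <- data.table::data.table(chrom = "chr1", pos = c(700L, 1050L),
                                  strand = "+")
  bm <- benchmark_known_pas(pk, known, threshold = 100L)
  expect_equal(bm$distances$distance, 50L)
  expect_equal(bm$fraction_within, 1)
  expect_error(benchmark_known_pas(pk, known[0]), "empty")
  # strand must match
  bm2 <- benchmark_known_pas(pk, data.table::data.table(
    chrom = "chr1", pos = 1050L, strand = "-"))
  expect_true(is.na(bm2$distances$distance))
})

test_that("benchmark distances are symmetric under coordinate mirroring", {
  set.seed(17)
  for (rep in 1:5) {
    edges <- sort(sample(100:1900, 5))
    sites <- sort(sample(100:1900, 8))
    pk <- data.table::rbindlist(lapply(seq_along(edges), function(i)
      mk_peak(edges[i], id = paste0("p", i))))
    known <- data.table::data.table(chrom = "chr1", pos = sites, strand = "+")
    bm <- benchmark_known_pas(pk, known)
    L <- 2000L
    pkm <- data.table::rbindlist(lapply(seq_along(edges), function(i)
      mk_peak(L - 1L - edges[i], strand = "-", id = paste0("p", i))))
    bmm <- benchmark_known_pas(pkm, data.table::data.table(
      chrom = "chr1", pos = L - 1L - sites, strand = "-"))
    expect_equal(bm$distances$distance, bmm$distances$distance)
  }
})

test_that("known set = truth with zero jitter gives full concordance", {
  cfg <- sim_config(n_genes = 15L, cells_per_cluster = 30L, jitter_sd = 0,
                    artifact_rate = 0, seed = 19L)
  ref <- generate_reference(cfg)
  tags <- simulate_tags(ref)
  pk <- call_peaks(tags, ref$annotation)
  known <- ref$truth$pas[kind == "true_pas",
                         .(chrom, pos = site, strand)]
  bm <- benchmark_known_pas(pk, known, threshold = 100L)
  expect_equal(bm$fraction_within, 1)
})
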