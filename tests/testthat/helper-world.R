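# Shared fixtures, built in code. tiny_world() is computed once per test run
# and reused by several files; tests that need a different world build their
# own config. Scales are kept small (20 genes, 30 cells/cluster) so the whole
# suite stays fast; acceptance tests use the full stated world where required.

.world_cache <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (!is.null(.world_cache$w)) return(.world_cache$w)
  cfg <- sim_config(n_genes = 20L, cells_per_cluster = 30L, seed = 7L)
  ref <- generate_reference(cfg)
  tags <- simulate_tags(ref)
  peaks <- call_peaks(tags, ref$annotation)
  cm <- build_count_matrices(peaks, tags, cells = TRUE,
                             clusters = cfg$cluster_ordering)
  fr_utr <- filter_peaks(cm$peaks, cm$cpm, ref$genome, "utr3")
  fr_int <- filter_peaks(cm$peaks, cm$cpm, ref$genome, "intron")
  kept <- rbind(fr_utr$kept, fr_int$kept)
  w <- list(cfg = cfg, ref = ref, tags = tags, peaks = peaks, cm = cm,
            fr_utr = fr_utr, fr_int = fr_int, kept = kept,
            groups = group_utr_peaks(kept))
  .world_cache$w <- w
  w
}

# tag table for hand-built cases
mk_tags <- function(pos, chrom = "chr1", strand = "+", cluster = "A",
                    barcode = paste0(cluster, "_c1")) {
  data.table::data.table(chrom = chrom, pos3 = as.integer(pos), strand = strand,
                         barcode = barcode, cluster = cluster)
}

mk_annotation <- function(start, end, chrom = "chr1", strand = "+",
                          gene_id = "gX", region_class = "utr3") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         gene_id = gene_id, region_class = region_class)
}
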