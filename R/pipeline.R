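# End-to-end orchestration. The defaults reproduce the stated analysis
# parameters: total CPM < 10 (3'UTR and intron), per-cluster CPM < 5 (intron
# only), A8 in 10-140 nt / A7 in 1-200 nt downstream windows, -30/+150 motif
# window, alpha = 0.05, BH FDR.

#' Pipeline configuration
#'
#' @param sim an [sim_config()] object (the input world when simulating).
#' @param min_coverage,merge_distance peak-caller parameters.
#' @param alpha significance threshold for dynamic-APA designation and
#'   direction calls.
#' @param motif_upstream,motif_downstream poly(A)-signal scan window (nt).
#' @param cell_level also compute cell-level pPUI and per-cell averages.
#' @param seed integer seed for the simulation stage.
#' @return object of class `apa_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            min_coverage = 5L, merge_distance = 25L,
                            alpha = 0.05,
                            motif_upstream = 30L, motif_downstream = 150L,
                            cell_level = TRUE, seed = 1L) {
  cfg <- list(sim = sim, min_coverage = as.integer(min_coverage),
              merge_distance = as.integer(merge_distance), alpha = alpha,
              motif_upstream = as.integer(motif_upstream),
              motif_downstream = as.integer(motif_downstream),
              cell_level = isTRUE(cell_level), seed = as.integer(seed))
  class(cfg) <- "apa_pipeline_config"
  cfg
}

#' Serialize / parse a pipeline configuration (JSON)
#'
#' Round-trip identity: `parse(serialize(cfg))` equals `cfg`.
#'
#' @param cfg an `apa_pipeline_config`.
#' @return JSON string.
#' @export
serialize_config <- function(cfg) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' @rdname serialize_config
#' @param json JSON string or path to a JSON file.
#' @export
parse_config <- function(json) {
  if (!grepl("^\\s*\\{", json)) json <- paste(readLines(json), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  sim <- do.call(sim_config, c(x$sim[setdiff(names(x$sim), "pas_per_utr")],
                               list(pas_per_utr = unlist(x$sim$pas_per_utr))))
  do.call(pipeline_config, c(list(sim = sim),
                             x[setdiff(names(x), c("sim"))]))
}

#' Run the full APA pipeline on a simulated world
#'
#' Stages in dependency order: simulate -> call peaks -> count -> filter
#' (3'UTR and intron rules) -> pPUI/iPUI matrices -> pairwise differential
#' tests along adjacent clusters of the ordering + omnibus dynamic-APA test ->
#' ROKU specificity calls -> motif QC. All tables are written to `outdir` with
#' a provenance header; deterministic given the config.
#'
#' @param config an [pipeline_config()] object.
#' @param outdir output directory (created); NULL skips writing.
#' @return result bundle (list), invisibly when writing.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- config
  cfg$sim$seed <- cfg$seed
  ref <- generate_reference(cfg$sim)
  tags <- simulate_tags(ref)
  peaks <- call_peaks(tags, ref$annotation, cfg$min_coverage, cfg$merge_distance)
  cm <- build_count_matrices(peaks, tags, cells = cfg$cell_level,
                             clusters = cfg$sim$cluster_ordering)
  fr_utr <- filter_peaks(cm$peaks, cm$cpm, ref$genome, "utr3")
  fr_int <- filter_peaks(cm$peaks, cm$cpm, ref$genome, "intron")
  kept <- rbind(fr_utr$kept, fr_int$kept)
  groups <- group_utr_peaks(kept)
  pui_cluster <- ppui_matrix(groups, cm$counts)
  ipui_cluster <- ipui_matrix(kept, cm$counts)
  units <- make_utr_units(groups, cm$counts)
  ordering <- cfg$sim$cluster_ordering
  pairwise <- lapply(seq_len(length(ordering) - 1L), function(i) {
    chi2_differential(units, ordering[i:(i + 1L)], alpha = cfg$alpha)
  })
  omnibus <- chi2_differential(units, ordering, alpha = cfg$alpha)
  dynamic <- omnibus[q < cfg$alpha, unit_id]
  spec <- if (nrow(pui_cluster) > 0L && ncol(pui_cluster) >= 3L)
    specific_events(pui_cluster) else NULL
  motif <- scan_polya_signals(kept, ref$genome,
                              cfg$motif_upstream, cfg$motif_downstream)
  res <- list(reference = ref, tags = tags, counts = cm,
              filter_utr3 = fr_utr, filter_intron = fr_int, peaks = kept,
              groups = groups, pui_cluster = pui_cluster,
              ipui_cluster = ipui_cluster, pairwise = pairwise,
              omnibus = omnibus, dynamic_units = dynamic, specific = spec,
              motif = motif, config = cfg)
  if (cfg$cell_level) {
    bcs <- attr(tags, "barcodes")
    res$pui_cell <- ppui_cell_matrix(groups, cm$cell_counts, bcs$barcode)
    res$cell_mean_ppui <- data.table(
      barcode = bcs$barcode, cluster = bcs$cluster,
      mean_ppui = summarize_cell_ppui(res$pui_cell))
  }
  if (!is.null(outdir)) {
    write_pipeline_outputs(res, outdir)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(config = fnv1a32(serialize_config(res$config)),
            seed = as.character(res$config$seed))
  write_sim_outputs(res$reference, res$tags, outdir)
  write_tsv(res$peaks, file.path(outdir, "peaks.tsv"), prov)
  write_tsv(data.table(peak_id = rownames(res$counts$counts),
                       res$counts$counts),
            file.path(outdir, "peak_counts.tsv"), prov)
  mat_dt <- function(m) data.table(unit_id = rownames(m), m)
  write_tsv(mat_dt(res$pui_cluster), file.path(outdir, "ppui_cluster.tsv"), prov)
  if (nrow(res$ipui_cluster) > 0L)
    write_tsv(mat_dt(res$ipui_cluster), file.path(outdir, "ipui_cluster.tsv"), prov)
  write_tsv(rbindlist(res$pairwise), file.path(outdir, "differential_pairwise.tsv"), prov)
  write_tsv(res$omnibus, file.path(outdir, "differential_omnibus.tsv"), prov)
  if (!is.null(res$specific)) {
    write_tsv(data.table(unit_id = rownames(res$specific$calls),
                         res$specific$calls),
              file.path(outdir, "roku_calls.tsv"), prov)
    write_tsv(data.table(cluster = names(res$specific$ratio),
                         ratio = res$specific$ratio),
              file.path(outdir, "specific_ratio.tsv"), prov)
  }
  write_tsv(res$motif$offsets, file.path(outdir, "motif_offsets.tsv"), prov)
  if (!is.null(res$cell_mean_ppui))
    write_tsv(res$cell_mean_ppui, file.path(outdir, "cell_mean_ppui.tsv"), prov)
  invisible(outdir)
}
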