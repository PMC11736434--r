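# PAS peak discovery: a transparent coverage-run caller. Within each annotated
# 3'UTR or intron interval, maximal runs of positions whose tag-3'-end coverage
# reaches min_coverage (gaps up to merge_distance closed) become peaks. The
# peak's 3' edge (edge3) is its strand-aware downstream-most covered base and
# serves as the inferred cleavage position.

#' Call PAS peaks from 3'-tag records
#'
#' @param tags tag data.table (`chrom`, `pos3`, `strand`, `barcode`, `cluster`).
#' @param annotation 0-based half-open `utr3`/`intron` intervals per gene
#'   (see [read_annotation()]); intervals must not overlap within one gene and
#'   region class.
#' @param min_coverage minimum tag-3'-end coverage for a position to seed a
#'   peak (default 5).
#' @param merge_distance close gaps of up to this many uncovered nt between
#'   covered runs (default 25).
#' @return data.table of peaks (`peak_id`, `gene_id`, `region_class`, `chrom`,
#'   `start`, `end`, `strand`, `edge3`) with attribute `discarded` = number of
#'   input tags not assignable to any peak.
#' @export
call_peaks <- function(tags, annotation, min_coverage = 5L, merge_distance = 25L) {
  if (nrow(annotation) == 0L) stop("empty annotation", call. = FALSE)
  unknown <- setdiff(unique(tags$chrom), unique(annotation$chrom))
  if (length(unknown))
    warning("tags on chromosome(s) absent from annotation skipped: ",
            paste(unknown, collapse = ", "))
  ann <- copy(annotation)
  setorder(ann, chrom, start)
  peaks <- vector("list", nrow(ann))
  assigned_tags <- 0L
  for (i in seq_len(nrow(ann))) {
    tt <- tags[chrom == ann$chrom[i] & strand == ann$strand[i] &
                 pos3 >= ann$start[i] & pos3 < ann$end[i]]
    if (nrow(tt) == 0L) next
    cov <- tt[, .N, by = pos3][N >= min_coverage][order(pos3)]
    if (nrow(cov) == 0L) next
    gap <- c(0L, diff(cov$pos3))
    run <- cumsum(gap > merge_distance + 1L)
    iv <- cov[, .(start = min(pos3), end = max(pos3) + 1L), by = .(run)]
    iv[, run := NULL]
    iv[, `:=`(chrom = ann$chrom[i], strand = ann$strand[i],
              gene_id = ann$gene_id[i], region_class = ann$region_class[i])]
    iv[, edge3 := if (ann$strand[i] == "+") end - 1L else start]
    # tally assigned tags (any tag whose pos3 falls inside a peak interval)
    for (r in seq_len(nrow(iv)))
      assigned_tags <- assigned_tags + tt[pos3 >= iv$start[r] & pos3 < iv$end[r], .N]
    peaks[[i]] <- iv
  }
  peaks <- rbindlist(peaks[!vapply(peaks, is.null, logical(1))])
  if (nrow(peaks) == 0L) {
    peaks <- data.table(peak_id = character(0), gene_id = character(0),
                        region_class = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), edge3 = integer(0))
    setattr(peaks, "discarded", nrow(tags))
    return(peaks[])
  }
  setorder(peaks, gene_id, region_class, start)
  peaks[, peak_id := paste0(gene_id, ":", region_class,
                            rowid(gene_id, region_class))]
  setcolorder(peaks, c("peak_id", "gene_id", "region_class", "chrom",
                       "start", "end", "strand", "edge3"))
  setattr(peaks, "discarded", nrow(tags) - assigned_tags)
  peaks[]
}

#' Build cluster-level (and optional cell-level) peak count matrices
#'
#' Each tag is assigned to at most one peak (the peak interval containing its
#' 3'-end position, matched on chrom and strand). Per-cluster library sizes are
#' the column sums of the assigned-count matrix and define the CPM view
#' `CPM(p,c) = count(p,c) / library_size(c) * 1e6`.
#'
#' @param peaks peak table from [call_peaks()] (or an imported peak table).
#' @param tags tag data.table.
#' @param cells if TRUE also return sparse per-cell counts.
#' @param clusters optional full cluster set; clusters without tags get a
#'   zero column with a warning.
#' @return object of class `apa_peak_counts`: list with `peaks`, `counts`
#'   (peaks x clusters integer matrix), `lib_sizes`, `cpm`, optionally
#'   `cell_counts` (data.table `peak_id`, `barcode`, `cluster`, `count`), and
#'   `discarded` (tags assigned to no peak).
#' @export
build_count_matrices <- function(peaks, tags, cells = FALSE, clusters = NULL) {
  pk <- copy(peaks)
  tg <- copy(tags)
  pk[, `:=`(pstart = start, pend = end)]
  tg[, `:=`(tpos = pos3, tpos2 = pos3)]
  py <- pk[, .(chrom, strand, peak_id, pstart, pend)]
  setkey(py, chrom, strand, pstart, pend)
  hits <- foverlaps(tg[, .(chrom, strand, barcode, cluster, tpos, tpos2)],
                    py,
                    by.x = c("chrom", "strand", "tpos", "tpos2"),
                    by.y = c("chrom", "strand", "pstart", "pend"),
                    type = "within", nomatch = NULL)
  # foverlaps treats intervals as closed; pend is half-open, drop tags at pend
  hits <- hits[tpos < pend]
  discarded <- nrow(tags) - nrow(hits)
  clus <- clusters %||% sort(unique(tags$cluster))
  missing_cl <- setdiff(clus, unique(hits$cluster))
  if (length(missing_cl) && !is.null(clusters))
    warning("cluster(s) without tags get zero columns: ",
            paste(missing_cl, collapse = ", "))
  tab <- hits[, .N, by = .(peak_id, cluster)]
  counts <- matrix(0L, nrow = nrow(peaks), ncol = length(clus),
                   dimnames = list(peaks$peak_id, clus))
  counts[cbind(match(tab$peak_id, peaks$peak_id), match(tab$cluster, clus))] <- tab$N
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    warning(sum(empty), " peak(s) with zero assigned tags dropped")
    counts <- counts[!empty, , drop = FALSE]
    pk_out <- peaks[!empty]
  } else pk_out <- copy(peaks)
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, pmax(lib, 1L), "/") * 1e6
  res <- list(peaks = pk_out, counts = counts, lib_sizes = lib, cpm = cpm,
              discarded = discarded)
  if (cells) {
    cc <- hits[, .(count = .N), by = .(peak_id, barcode, cluster)]
    res$cell_counts <- cc[peak_id %in% pk_out$peak_id]
  }
  structure(res, class = "apa_peak_counts")
}

#' @export
print.apa_peak_counts <- function(x, ...) {
  cat("apa_peak_counts:", nrow(x$counts), "peaks x", ncol(x$counts),
      "clusters;", x$discarded, "unassigned tags\n")
  cat("  region classes:", paste(sprintf("%s=%d",
      names(table(x$peaks$region_class)), table(x$peaks$region_class)),
      collapse = ", "), "\n")
  invisible(x)
}
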