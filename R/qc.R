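# Credibility filters and motif QC. The internal-priming rule removes peaks
# with a long genomic adenine run on the sense strand just downstream of the
# peak 3' edge (the footprint oligo-dT can prime on); CPM rules remove weakly
# supported peaks. Rule sets differ between 3'UTR and intronic peaks:
#   utr3:   total CPM over all clusters < 10; A-run >= 8 starting 10-140 nt
#           downstream of edge3.
#   intron: CPM < 5 in any cluster; total CPM < 10; A-run >= 7 starting
#           1-200 nt downstream of edge3.

filter_rules <- function(region_class) {
  if (region_class == "utr3") {
    list(total_cpm = 10, cluster_cpm = NA_real_, a_len = 8L,
         win_from = 10L, win_to = 140L)
  } else {
    list(total_cpm = 10, cluster_cpm = 5, a_len = 7L,
         win_from = 1L, win_to = 200L)
  }
}

# TRUE when a sense-strand A-run of length >= a_len starts at a sense offset in
# [win_from, win_to] downstream of edge3; window truncated at chromosome ends.
has_downstream_a_run <- function(genome, chrom, strand, edge3, a_len,
                                 win_from, win_to) {
  w <- sense_window(genome, chrom, strand, edge3, win_from, win_to + a_len - 1L)
  if (nchar(w$seq) < a_len) return(FALSE)
  runs <- char_runs(w$seq, "A")
  if (nrow(runs) == 0L) return(FALSE)
  starts <- w$rel_from + runs$start - 1L
  any(runs$len >= a_len & starts >= win_from & starts <= win_to)
}

#' Filter peaks with CPM and internal-priming rules
#'
#' A peak is removed iff it violates any rule applicable to its region class;
#' the report itemizes removals per rule (a peak violating two rules is counted
#' once under each).
#'
#' @param peaks peak table (rows of one `region_class`, or pass `region_class`
#'   to subset).
#' @param cpm CPM matrix (peaks x clusters), rownames = peak ids; e.g. the
#'   `cpm` element of [build_count_matrices()].
#' @param genome named character vector of chromosome sequences.
#' @param region_class `"utr3"` or `"intron"`; selects the rule set.
#' @return object of class `apa_filter_report`: list with `kept` (peak table),
#'   `removed` (peak_id + logical column per rule), `n_removed_by_rule`,
#'   `n_input`.
#' @export
filter_peaks <- function(peaks, cpm, genome,
                         region_class = c("utr3", "intron")) {
  rclass <- match.arg(region_class)
  pk <- peaks[peaks$region_class == rclass]
  if (nrow(pk) == 0L) {
    rep0 <- list(kept = pk, removed = data.table(peak_id = character(0)),
                 n_removed_by_rule = integer(0), n_input = 0L)
    return(structure(rep0, class = "apa_filter_report"))
  }
  rules <- filter_rules(rclass)
  x <- cpm[pk$peak_id, , drop = FALSE]
  low_total <- rowSums(x) < rules$total_cpm
  low_cluster <- if (is.na(rules$cluster_cpm)) rep(FALSE, nrow(pk)) else
    apply(x, 1, min) < rules$cluster_cpm
  priming <- vapply(seq_len(nrow(pk)), function(i) {
    has_downstream_a_run(genome, pk$chrom[i], pk$strand[i], pk$edge3[i],
                         rules$a_len, rules$win_from, rules$win_to)
  }, logical(1))
  flags <- data.table(peak_id = pk$peak_id, low_total_cpm = low_total,
                      internal_priming = priming)
  if (!is.na(rules$cluster_cpm)) flags[, low_cluster_cpm := low_cluster]
  bad <- low_total | low_cluster | priming
  nrem <- colSums(as.matrix(flags[, -1]))
  structure(list(kept = pk[!bad], removed = flags[bad],
                 n_removed_by_rule = nrem, n_input = nrow(pk)),
            class = "apa_filter_report")
}

#' @export
print.apa_filter_report <- function(x, ...) {
  cat("apa_filter_report:", x$n_input, "peaks in,", nrow(x$kept), "kept\n")
  for (r in names(x$n_removed_by_rule))
    cat(sprintf("  %-18s %d removed\n", r, x$n_removed_by_rule[[r]]))
  invisible(x)
}

#' Scan poly(A) signal motifs around peak 3' edges
#'
#' Sense-strand scan of the window from `upstream` nt upstream to `downstream`
#' nt downstream of each peak's 3' edge. Every motif occurrence is recorded as
#' the offset of its last base relative to edge3 (negative = upstream). A
#' peak's canonical flag is TRUE when AATAAA or ATTAAA hits anywhere in the
#' window.
#'
#' @param peaks peak table.
#' @param genome named character vector of chromosome sequences.
#' @param upstream,downstream window extent in nt (defaults 30/150).
#' @param motifs named character vector of DNA motifs to scan.
#' @return object of class `apa_motif_profile`: list with `offsets` (data.table
#'   `peak_id`, `motif`, `offset`), `flags` (data.table `peak_id`,
#'   `canonical`), and the window.
#' @export
scan_polya_signals <- function(peaks, genome, upstream = 30L, downstream = 150L,
                               motifs = c(AATAAA = "AATAAA", ATTAAA = "ATTAAA")) {
  if (is.null(names(motifs))) names(motifs) <- motifs
  offs <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    w <- sense_window(genome, peaks$chrom[i], peaks$strand[i], peaks$edge3[i],
                      -upstream, downstream)
    if (nchar(w$seq) == 0L) next
    rows <- lapply(names(motifs), function(mn) {
      m <- gregexpr(motifs[[mn]], w$seq, fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      data.table(peak_id = peaks$peak_id[i], motif = mn,
                 offset = w$rel_from + as.integer(m) - 1L + nchar(motifs[[mn]]) - 1L)
    })
    offs[[i]] <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  }
  offsets <- rbindlist(offs[!vapply(offs, is.null, logical(1))])
  if (nrow(offsets) == 0L)
    offsets <- data.table(peak_id = character(0), motif = character(0),
                          offset = integer(0))
  canon <- offsets[motif %in% c("AATAAA", "ATTAAA"), unique(peak_id)]
  flags <- data.table(peak_id = peaks$peak_id,
                      canonical = peaks$peak_id %in% canon)
  structure(list(offsets = offsets, flags = flags,
                 upstream = upstream, downstream = downstream),
            class = "apa_motif_profile")
}

#' Compare two motif-offset densities with a two-sample KS test
#'
#' Both offset samples are restricted to `[-window, window]` around the peak
#' 3' edge before testing.
#'
#' @param offsets_a,offsets_b numeric vectors of motif-end offsets.
#' @param window half-width of the comparison window in nt (default 100).
#' @return list with `D` (KS statistic) and `p.value`.
#' @export
compare_signal_density <- function(offsets_a, offsets_b, window = 100L) {
  a <- offsets_a[abs(offsets_a) <= window]
  b <- offsets_b[abs(offsets_b) <= window]
  if (length(a) == 0L || length(b) == 0L)
    stop("empty offset sample after windowing", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p.value = kt$p.value)
}

#' Benchmark peak 3' edges against a known-PAS catalogue
#'
#' For each peak, the signed transcription-direction distance from edge3 to the
#' nearest known site on the same chromosome and strand (positive = the known
#' site lies downstream of the edge).
#'
#' @param peaks peak table.
#' @param known data.table (`chrom`, `pos`, `strand`), e.g. from
#'   [read_known_pas_bed()].
#' @param threshold concordance distance in nt (default 100).
#' @return object of class `apa_benchmark`: list with `distances` (data.table
#'   `peak_id`, `distance`; NA when no same-chrom/strand site exists) and
#'   `fraction_within` (share of peaks with a defined distance <= threshold).
#' @export
benchmark_known_pas <- function(peaks, known, threshold = 100L) {
  if (nrow(known) == 0L) stop("empty known-PAS set", call. = FALSE)
  dist <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- known[chrom == peaks$chrom[i] & strand == peaks$strand[i], pos]
    if (length(cand) == 0L) next
    d <- cand - peaks$edge3[i]
    if (peaks$strand[i] == "-") d <- -d
    dist[i] <- d[which.min(abs(d))]
  }
  ok <- !is.na(dist)
  structure(list(distances = data.table(peak_id = peaks$peak_id, distance = dist),
                 fraction_within = mean(abs(dist[ok]) <= threshold),
                 threshold = threshold),
            class = "apa_benchmark")
}
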