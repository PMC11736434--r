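# Proximal PAS usage index (pPUI) and intronic PAS usage index (iPUI).
#
#   pPUI = log2[ (C1 + 1) / <C + 1> ]
#
# where C1 is the read count of the proximal peak of a multi-PAS 3'UTR and
# <C + 1> the geometric mean of the pseudocounted counts of all its peaks.
# Higher pPUI = preference for the proximal PAS = shorter 3'UTR.
#
#   iPUI = log2[ (Ci + 1) / (Cu + 1) ]
#
# where Ci is the count of one intronic peak and Cu the summed count of the
# gene's 3'UTR peaks in the same column. Higher iPUI = more intronic cleavage.

#' Group multi-PAS 3'UTR peaks into proximal-to-distal units
#'
#' One unit per 3'UTR with >= 2 peaks, peaks ordered in transcription
#' direction (index 1 = proximal: smallest edge3 on `+`, largest on `-`).
#' Single-peak 3'UTRs are excluded and tallied in attribute `single_pas`.
#'
#' @param peaks filtered peak table (only `region_class == "utr3"` rows used).
#' @return named list of units, each a list(`unit_id`, `gene_id`, `strand`,
#'   `peak_ids` in proximal-to-distal order).
#' @export
group_utr_peaks <- function(peaks) {
  pk <- peaks[peaks$region_class == "utr3"]
  units <- list()
  singles <- 0L
  for (g in unique(pk$gene_id)) {
    gp <- pk[gene_id == g]
    if (length(unique(gp$strand)) > 1L)
      stop("peaks of one 3'UTR on mixed strands: ", g, call. = FALSE)
    if (nrow(gp) < 2L) { singles <- singles + 1L; next }
    ord <- order(gp$edge3, decreasing = gp$strand[1] == "-")
    units[[g]] <- list(unit_id = g, gene_id = g, strand = gp$strand[1],
                       peak_ids = gp$peak_id[ord])
  }
  setattr(units, "single_pas", singles)
  units
}

#' Proximal PAS usage index of one count vector or matrix
#'
#' @param counts numeric vector (peaks in proximal-to-distal order) or matrix
#'   (peaks x columns) of raw counts; row 1 is the proximal peak.
#' @return numeric pPUI (scalar, or one value per column).
#' @export
ppui <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 2, ppui))
  log2((counts[1] + 1) / exp(mean(log(counts + 1))))
}

#' Cluster-level pPUI matrix
#'
#' @param groups units from [group_utr_peaks()].
#' @param counts peaks x clusters count matrix (rownames = peak ids).
#' @return units x clusters numeric matrix of pPUI values (always defined:
#'   cluster-level counts are pseudocounted).
#' @export
ppui_matrix <- function(groups, counts) {
  out <- t(vapply(groups, function(u) ppui(counts[u$peak_ids, , drop = FALSE]),
                  numeric(ncol(counts))))
  dimnames(out) <- list(names(groups), colnames(counts))
  out
}

#' Cell-level pPUI matrix
#'
#' A cell's entry for a unit is defined only when the cell has at least one
#' read in the unit; empty cells are NA (pseudocounting them would pin pPUI at
#' 0 and fabricate signal).
#'
#' @param groups units from [group_utr_peaks()].
#' @param cell_counts sparse per-cell counts (`peak_id`, `barcode`, `count`),
#'   e.g. the `cell_counts` element of [build_count_matrices()].
#' @param barcodes character vector of all cell barcodes (columns).
#' @return units x cells numeric matrix with NA for empty unit/cell pairs.
#' @export
ppui_cell_matrix <- function(groups, cell_counts, barcodes) {
  out <- matrix(NA_real_, nrow = length(groups), ncol = length(barcodes),
                dimnames = list(names(groups), barcodes))
  cc <- cell_counts[barcode %in% barcodes]
  for (u in groups) {
    sub <- cc[peak_id %in% u$peak_ids]
    if (nrow(sub) == 0L) next
    m <- matrix(0L, nrow = length(u$peak_ids), ncol = length(barcodes),
                dimnames = list(u$peak_ids, barcodes))
    m[cbind(match(sub$peak_id, u$peak_ids), match(sub$barcode, barcodes))] <- sub$count
    nonzero <- colSums(m) > 0L
    if (any(nonzero))
      out[u$unit_id, nonzero] <- ppui(m[, nonzero, drop = FALSE])
  }
  out
}

#' Intronic PAS usage index
#'
#' @param ci count(s) of the intronic peak.
#' @param cu summed count(s) of the same gene's 3'UTR peaks in the same column.
#' @return numeric iPUI value(s): `log2((ci + 1) / (cu + 1))`.
#' @export
ipui <- function(ci, cu) log2((ci + 1) / (cu + 1))

#' Cluster-level iPUI matrix
#'
#' One unit per intronic peak (a gene with two intronic peaks yields two
#' units); Cu is the sum of the gene's surviving 3'UTR peak counts.
#'
#' @param peaks peak table containing both `intron` and `utr3` rows (filtered).
#' @param counts peaks x clusters count matrix.
#' @return units x clusters iPUI matrix (may have zero rows).
#' @export
ipui_matrix <- function(peaks, counts) {
  ip <- peaks[peaks$region_class == "intron"]
  up <- peaks[peaks$region_class == "utr3"]
  if (nrow(ip) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = ncol(counts),
                  dimnames = list(NULL, colnames(counts))))
  out <- matrix(NA_real_, nrow = nrow(ip), ncol = ncol(counts),
                dimnames = list(ip$peak_id, colnames(counts)))
  for (i in seq_len(nrow(ip))) {
    upk <- up[gene_id == ip$gene_id[i], peak_id]
    cu <- if (length(upk)) colSums(counts[upk, , drop = FALSE]) else
      rep(0, ncol(counts))
    out[i, ] <- ipui(counts[ip$peak_id[i], ], cu)
  }
  out
}

#' Per-cell average pPUI over a unit subset
#'
#' @param cell_ppui units x cells matrix from [ppui_cell_matrix()].
#' @param units optional character vector restricting to a unit subset.
#' @return named numeric vector (one mean per cell, NA when the cell has no
#'   eligible unit).
#' @export
summarize_cell_ppui <- function(cell_ppui, units = NULL) {
  m <- if (is.null(units)) cell_ppui else cell_ppui[units, , drop = FALSE]
  res <- colMeans(m, na.rm = TRUE)
  res[colSums(!is.na(m)) == 0L] <- NA_real_
  res
}
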