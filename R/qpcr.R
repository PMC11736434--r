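# qPCR validation of PAS-specific transcripts. Relative expression (RE) of an
# assay is 2^(Cq_ref - Cq_assay) against the reference transcript (ACTB in the
# wet-lab scheme), assuming a doubling per cycle. RE_pPAS comparisons between
# two cell types use the composite ratio (p2/p1) / (d2/d1): > 1 means the
# proximal isoform gained relative to the distal one, i.e. 3'UTR shortening in
# cell type 2.

#' Read a Cq table
#'
#' Expected columns: `sample`, `cell_type`, `assay` (values `proximal`,
#' `distal`, `reference`), `replicate`, `cq`.
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_cq_table <- function(path) {
  cq <- read_tsv(path)
  need <- c("sample", "cell_type", "assay", "replicate", "cq")
  if (!all(need %in% names(cq)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cq
}

#' Relative expression from Cq values
#'
#' `RE = efficiency^(mean Cq_ref - mean Cq_assay)` per (sample, cell_type,
#' assay), with the replicate SD of the assay Cq reported.
#'
#' @param cq Cq table (see [read_cq_table()]); Cq values must be positive and
#'   every sample needs at least one `reference` assay row.
#' @param efficiency amplification efficiency (fold change per cycle,
#'   default 2).
#' @return object of class `apa_re_result`: list with `re` (data.table
#'   `sample`, `cell_type`, `assay`, `re`, `cq_mean`, `cq_sd`, `n_rep`) and
#'   `replicate_re` (per-replicate RE values, replicates paired with the
#'   reference by index).
#' @export
compute_relative_expression <- function(cq, efficiency = 2) {
  stopifnot(all(cq$cq > 0))
  for (s in unique(cq$sample))
    if (nrow(cq[sample == s & assay == "reference"]) == 0L)
      stop("sample '", s, "' has no reference assay", call. = FALSE)
  refm <- cq[assay == "reference",
             .(cq_ref = mean(cq)), by = .(sample, cell_type)]
  assays <- cq[assay != "reference"]
  re <- assays[, .(cq_mean = mean(cq), cq_sd = sd(cq), n_rep = .N),
               by = .(sample, cell_type, assay)]
  re <- merge(re, refm, by = c("sample", "cell_type"))
  re[, re := efficiency^(cq_ref - cq_mean)]
  # replicate-level RE: pair assay and reference replicates by replicate index
  refrep <- cq[assay == "reference",
               .(sample, cell_type, replicate, cq_ref_rep = cq)]
  reprep <- merge(assays, refrep, by = c("sample", "cell_type", "replicate"))
  reprep[, re_rep := efficiency^(cq_ref_rep - cq)]
  structure(list(re = re[], replicate_re = reprep[], efficiency = efficiency),
            class = "apa_re_result")
}

#' Compare RE_pPAS between two cell types
#'
#' Composite ratio `(p2/p1) / (d2/d1)` from replicate-mean REs; the verdict is
#' `shortening` in `cell_type_2` when the ratio exceeds 1 with a two-sided
#' Welch t-test `p < 0.05` on the replicate-level log2(proximal/distal)
#' values, `lengthening` below 1, `inconclusive` otherwise (or with a single
#' replicate, where p is NA).
#'
#' @param re an `apa_re_result` from [compute_relative_expression()].
#' @param cell_type_1,cell_type_2 cell-type labels present in the table.
#' @param alpha significance threshold (default 0.05).
#' @return data.table per sample: `proximal_ratio` (p2/p1), `distal_ratio`
#'   (d2/d1), `composite_ratio`, `p.value`, `verdict`.
#' @export
compare_re_ppas <- function(re, cell_type_1, cell_type_2, alpha = 0.05) {
  tab <- re$re
  rep_tab <- re$replicate_re
  out <- vector("list", length(unique(tab$sample)))
  for (i in seq_along(unique(tab$sample))) {
    s <- unique(tab$sample)[i]
    g <- function(ct, as) tab[sample == s & cell_type == ct & assay == as, re]
    need <- c(g(cell_type_1, "proximal"), g(cell_type_1, "distal"),
              g(cell_type_2, "proximal"), g(cell_type_2, "distal"))
    if (length(need) != 4L)
      stop("both cell types need proximal and distal assays in sample ", s,
           call. = FALSE)
    pr <- g(cell_type_2, "proximal") / g(cell_type_1, "proximal")
    dr <- g(cell_type_2, "distal") / g(cell_type_1, "distal")
    comp <- pr / dr
    # replicate-level log2(proximal/distal) per cell type
    w <- function(ct) {
      r <- rep_tab[sample == s & cell_type == ct]
      wide <- dcast(r, replicate ~ assay, value.var = "re_rep")
      log2(wide$proximal / wide$distal)
    }
    w1 <- w(cell_type_1); w2 <- w(cell_type_2)
    p <- if (length(w1) >= 2L && length(w2) >= 2L)
      t.test(w2, w1)$p.value else NA_real_
    verdict <- if (!is.na(p) && p < alpha && comp > 1) "shortening"
               else if (!is.na(p) && p < alpha && comp < 1) "lengthening"
               else "inconclusive"
    out[[i]] <- data.table(sample = s, proximal_ratio = pr, distal_ratio = dr,
                           composite_ratio = comp, p.value = p,
                           verdict = verdict)
  }
  rbindlist(out)
}
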