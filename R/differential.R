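# Differential PAS usage: Pearson chi-squared tests on peak-count contingency
# tables (peaks x clusters), Benjamini-Hochberg FDR across tested units,
# shortening/lengthening classification from the sign of the index change, and
# the set algebra used to define mutually dynamic APA events.

# Pearson chi2 without continuity correction. All-zero rows are dropped (their
# expected counts are zero); returns NULL if fewer than 2 rows/cols remain or
# any column total is zero.
chi2_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L || any(colSums(tab) == 0)) return(NULL)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up rule: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1,
#' order-preserving.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values in the original order.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  qs <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- qs
  q
}

#' Classify a significant pPUI change as shortening or lengthening
#'
#' Shortening in the second population when `q < alpha` and the index
#' increases; lengthening when it decreases; `none` otherwise.
#'
#' @param q BH-adjusted p-value(s).
#' @param delta index change (second minus first population).
#' @param alpha significance threshold (default 0.05).
#' @return character vector in `{shortening, lengthening, none}`.
#' @export
classify_direction <- function(q, delta, alpha = 0.05) {
  out <- rep("none", length(q))
  sig <- !is.na(q) & q < alpha
  out[sig & delta > 0] <- "shortening"
  out[sig & delta < 0] <- "lengthening"
  out
}

#' Chi-squared differential PAS usage across units
#'
#' Pairwise mode (two columns selected) tests each unit's peaks x 2 count
#' table and classifies direction from the pPUI/iPUI change; omnibus mode
#' (all columns) defines dynamic-APA units at `q < alpha`. Units with a
#' zero-total column (or fewer than two non-empty peaks) are skipped and
#' tallied in attribute `skipped`.
#'
#' @param unit_tables named list of count matrices (peaks x clusters), one per
#'   unit, e.g. from [make_utr_units()] or [make_intron_units()].
#' @param columns character vector of cluster columns to test: length 2 for a
#'   pairwise comparison, or all columns for the omnibus test (default).
#' @param alpha significance threshold for the direction call / dynamic set.
#' @param index_fun function mapping a unit's count vector (one column) to its
#'   usage index; default [ppui()]. Used for the direction call in pairwise
#'   mode.
#' @return data.table (`unit_id`, `comparison`, `chi2`, `df`, `p`, `q`,
#'   `delta`, `direction`) with attribute `skipped` (unit ids not testable).
#' @export
chi2_differential <- function(unit_tables, columns = NULL, alpha = 0.05,
                              index_fun = ppui) {
  if (length(unit_tables) == 0L)
    return(data.table(unit_id = character(0), comparison = character(0),
                      chi2 = numeric(0), df = integer(0), p = numeric(0),
                      q = numeric(0), delta = numeric(0),
                      direction = character(0)))
  cols <- columns %||% colnames(unit_tables[[1]])
  pairwise <- length(cols) == 2L
  comparison <- if (pairwise) paste(cols, collapse = " vs ") else "omnibus"
  rows <- vector("list", length(unit_tables))
  skipped <- character(0)
  for (i in seq_along(unit_tables)) {
    uid <- names(unit_tables)[i]
    tab <- unit_tables[[i]][, cols, drop = FALSE]
    st <- chi2_stat(tab)
    if (is.null(st)) { skipped <- c(skipped, uid); next }
    delta <- if (pairwise) index_fun(tab[, 2]) - index_fun(tab[, 1]) else NA_real_
    rows[[i]] <- data.table(unit_id = uid, comparison = comparison,
                            chi2 = st$chi2, df = st$df,
                            p = pchisq(st$chi2, st$df, lower.tail = FALSE),
                            delta = delta)
  }
  res <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(res) > 0L) {
    res[, q := adjust_bh(p)]
    res[, direction := if (pairwise) classify_direction(q, delta, alpha)
        else "none"]
    setcolorder(res, c("unit_id", "comparison", "chi2", "df", "p", "q",
                       "delta", "direction"))
  }
  setattr(res, "skipped", skipped)
  res[]
}

#' Per-unit count tables for multi-PAS 3'UTRs
#'
#' @param groups units from [group_utr_peaks()].
#' @param counts peaks x clusters count matrix.
#' @return named list of count matrices (peaks in proximal-to-distal order).
#' @export
make_utr_units <- function(groups, counts) {
  setNames(lapply(groups, function(u) counts[u$peak_ids, , drop = FALSE]),
           names(groups))
}

#' Per-unit count tables for intronic peaks
#'
#' Each unit is one intronic peak against the summed 3'UTR counts of its gene
#' (rows `intron`, `utr3`), matching the iPUI definition; pass
#' `index_fun = function(v) ipui(v[1], v[2])` to [chi2_differential()].
#'
#' @param peaks filtered peak table with `intron` and `utr3` rows.
#' @param counts peaks x clusters count matrix.
#' @return named list of 2 x clusters count matrices.
#' @export
make_intron_units <- function(peaks, counts) {
  ip <- peaks[peaks$region_class == "intron"]
  up <- peaks[peaks$region_class == "utr3"]
  units <- list()
  for (i in seq_len(nrow(ip))) {
    upk <- up[gene_id == ip$gene_id[i], peak_id]
    cu <- if (length(upk)) colSums(counts[upk, , drop = FALSE]) else
      rep(0L, ncol(counts))
    units[[ip$peak_id[i]]] <- rbind(intron = counts[ip$peak_id[i], ],
                                    utr3 = cu)
  }
  units
}

#' Compare index distributions between groups
#'
#' @param values numeric vector of index values (e.g. per-cell average pPUI).
#' @param group grouping vector (2 groups for `t`/`ks`, >= 2 for `kruskal`).
#' @param method `"t"` (Welch two-sided), `"ks"` (two-sample) or `"kruskal"`
#'   (tie-corrected H).
#' @return list with `statistic`, `p.value`, `method`.
#' @export
compare_pui_distributions <- function(values, group,
                                      method = c("t", "ks", "kruskal")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group[keep])
  gs <- split(values, group)
  if (method %in% c("t", "ks") && length(gs) != 2L)
    stop("exactly two groups required for method '", method, "'", call. = FALSE)
  if (method == "kruskal" && length(gs) < 2L)
    stop("at least two groups required for Kruskal-Wallis", call. = FALSE)
  res <- switch(method,
    t = {
      if (any(lengths(gs) < 2L))
        stop("each group needs >= 2 values for the t-test", call. = FALSE)
      ht <- t.test(gs[[1]], gs[[2]])
      list(statistic = unname(ht$statistic), p.value = ht$p.value)
    },
    ks = {
      ht <- suppressWarnings(ks.test(gs[[1]], gs[[2]], exact = FALSE))
      list(statistic = unname(ht$statistic), p.value = ht$p.value)
    },
    kruskal = {
      ht <- kruskal.test(values, factor(group))
      list(statistic = unname(ht$statistic), p.value = ht$p.value)
    })
  c(res, list(method = method))
}

#' Trend summary along a differentiation ordering
#'
#' For every adjacent cluster pair of the ordering: the mean per-cell average
#' pPUI of each cluster, a Welch t-test between the two cell populations, and
#' the counts of significant two-PAS units shortening vs lengthening in the
#' later cluster.
#'
#' @param cell_mean_ppui numeric vector of per-cell average pPUI values.
#' @param cell_cluster cluster label per cell (aligned with `cell_mean_ppui`).
#' @param ordering ordered cluster labels.
#' @param unit_tables per-unit count tables (see [chi2_differential()]).
#' @param alpha significance threshold for direction calls (default 0.05).
#' @return data.table, one row per adjacent pair: `mean_a`, `mean_b`,
#'   `t`, `p`, `n_shortening`, `n_lengthening` (two-PAS units only).
#' @export
trend_summary <- function(cell_mean_ppui, cell_cluster, ordering,
                          unit_tables, alpha = 0.05) {
  two_pas <- names(unit_tables)[vapply(unit_tables, nrow, 0L) == 2L]
  rows <- lapply(seq_len(length(ordering) - 1L), function(i) {
    a <- ordering[i]; b <- ordering[i + 1L]
    va <- cell_mean_ppui[cell_cluster == a]
    vb <- cell_mean_ppui[cell_cluster == b]
    ht <- t.test(vb[!is.na(vb)], va[!is.na(va)])
    d <- chi2_differential(unit_tables, c(a, b), alpha = alpha)
    d2 <- d[unit_id %in% two_pas]
    data.table(comparison = paste(a, "vs", b),
               mean_a = mean(va, na.rm = TRUE), mean_b = mean(vb, na.rm = TRUE),
               t = unname(ht$statistic), p = ht$p.value,
               n_shortening = d2[direction == "shortening", .N],
               n_lengthening = d2[direction == "lengthening", .N])
  })
  rbindlist(rows)
}

#' Mutually dynamic APA set and Venn region sizes
#'
#' Computes `A` intersected with the union of `B` and `C` (the construction
#' used to define APA events shared between two lineages) plus the sizes of
#' all seven Venn regions.
#'
#' @param set_a,set_b,set_c character vectors of unit ids.
#' @return list with `mutual` (sorted character vector) and `venn` (named
#'   integer vector of the 7 disjoint region sizes).
#' @export
mutual_dynamic_set <- function(set_a, set_b, set_c) {
  a <- unique(set_a); b <- unique(set_b); cc <- unique(set_c)
  mutual <- sort(intersect(a, union(b, cc)))
  all3 <- union(a, union(b, cc))
  ina <- all3 %in% a; inb <- all3 %in% b; inc <- all3 %in% cc
  venn <- c(
    A_only = sum(ina & !inb & !inc),
    B_only = sum(!ina & inb & !inc),
    C_only = sum(!ina & !inb & inc),
    AB = sum(ina & inb & !inc),
    AC = sum(ina & !inb & inc),
    BC = sum(!ina & inb & inc),
    ABC = sum(ina & inb & inc))
  list(mutual = mutual, venn = venn)
}
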