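# ROKU-style specificity calls: subtract a one-step Tukey-biweight location,
# take absolute values, compute Shannon entropy as a nonspecificity score, and
# assign per-column outlier codes {-1, 0, 1} by an AIC-minimizing search over
# how many low-side (s) and high-side (l) extremes to label. Applied to pPUI
# matrices: +1 = specifically high pPUI (shortened 3'UTR), -1 = specifically
# low pPUI (lengthened 3'UTR), 0 = nonspecific. For iPUI matrices +1/-1 read
# as enhanced/attenuated intronic cleavage.

#' One-step Tukey-biweight location estimate
#'
#' `u_i = (x_i - median) / (c * MAD + eps)` with MAD the unscaled median
#' absolute deviation; weights `(1 - u^2)^2` for `|u| < 1`, 0 otherwise;
#' returns the weighted mean.
#'
#' @param x numeric vector (n >= 1, finite).
#' @param c biweight tuning constant (default 5).
#' @param eps guard against zero MAD (default 1e-4).
#' @return scalar location estimate.
#' @export
tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  med <- median(x)
  s <- median(abs(x - med))
  u <- (x - med) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Processed vector and Shannon entropy of the ROKU procedure
#'
#' `x'_i = |x_i - tukey_biweight(x)|`, normalized to probabilities; entropy in
#' bits with `0 * log(0) = 0`. A constant vector (all `x'` zero) carries no
#' specificity information and gets the maximal entropy `log2(n)`.
#'
#' @param x numeric vector (n >= 2).
#' @return list with `xprime` and `H`.
#' @export
roku_entropy <- function(x) {
  stopifnot(length(x) >= 2L)
  xp <- abs(x - tukey_biweight(x))
  tot <- sum(xp)
  if (tot == 0) return(list(xprime = xp, H = log2(length(x))))
  p <- xp / tot
  nz <- p > 0
  list(xprime = xp, H = -sum(p[nz] * log2(p[nz])))
}

#' AIC-based outlier assignment over sorted extremes
#'
#' For every split (s low-side, l high-side outliers, `s + l <= n - 2`) the
#' inlier variance (MLE) gives `AIC(s,l) = (n-s-l) * ln(sigma2) + 2(s+l+1)`;
#' the minimizing split labels the s smallest values -1, the l largest +1 and
#' the rest 0. AIC ties resolve toward fewer outliers (then fewer low-side).
#'
#' @param x numeric vector (n >= 3).
#' @return integer vector of calls in `{-1, 0, 1}` aligned with `x`.
#' @export
roku_call_outliers <- function(x) {
  n <- length(x)
  stopifnot(n >= 3L)
  calls <- integer(n)
  if (var(x) == 0) return(calls)
  o <- order(x)
  xs <- x[o]
  best <- list(aic = Inf, s = 0L, l = 0L)
  for (tot in 0:(n - 2L)) {
    for (s in 0:tot) {
      l <- tot - s
      inl <- xs[(s + 1L):(n - l)]
      m <- length(inl)
      sigma2 <- sum((inl - mean(inl))^2) / m
      aic <- m * log(sigma2) + 2 * (s + l + 1)
      if (aic < best$aic) best <- list(aic = aic, s = s, l = l)
    }
  }
  if (best$s > 0L) calls[o[seq_len(best$s)]] <- -1L
  if (best$l > 0L) calls[o[(n - best$l + 1L):n]] <- 1L
  calls
}

#' ROKU table for a units x clusters matrix
#'
#' @param mat numeric matrix (rows = units, columns = clusters), complete.
#' @return list with `table` (data.table `unit_id`, `H`) and `calls`
#'   (integer matrix of per-cluster codes in `{-1, 0, 1}`).
#' @export
roku <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 3L)
  H <- apply(mat, 1, function(x) roku_entropy(x)$H)
  calls <- t(apply(mat, 1, roku_call_outliers))
  dimnames(calls) <- dimnames(mat)
  list(table = data.table(unit_id = rownames(mat), H = H), calls = calls)
}

#' Cell-type- or stage-specific APA events from an index matrix
#'
#' Runs the ROKU outlier calls per unit and collects, per cluster (or per
#' stage after column averaging with `stage_map`), the sets of units called
#' +1 (specifically shortened 3'UTR for pPUI; enhanced intronic cleavage for
#' iPUI) and -1 (lengthened / attenuated), plus their ratio.
#'
#' @param mat units x clusters index matrix (complete at cluster level).
#' @param stage_map optional named character vector mapping every cluster to a
#'   stage label; columns are averaged per stage before calling.
#' @return object of class `apa_specific_events`: list with `calls` matrix,
#'   `events` (per column: `shortening`/`lengthening` unit-id vectors) and
#'   `ratio` (shortening count / lengthening count; Inf when the denominator
#'   is 0, NA when both sets are empty).
#' @export
specific_events <- function(mat, stage_map = NULL) {
  if (!is.null(stage_map)) {
    if (!all(colnames(mat) %in% names(stage_map)))
      stop("stage_map must map every cluster exactly once", call. = FALSE)
    stages <- unique(unname(stage_map[colnames(mat)]))
    mat <- vapply(stages, function(st) {
      rowMeans(mat[, stage_map[colnames(mat)] == st, drop = FALSE])
    }, numeric(nrow(mat)))
    colnames(mat) <- stages
  }
  rk <- roku(mat)
  cols <- colnames(mat)
  events <- lapply(cols, function(cc) list(
    shortening = rownames(mat)[rk$calls[, cc] == 1L],
    lengthening = rownames(mat)[rk$calls[, cc] == -1L]))
  names(events) <- cols
  ratio <- vapply(events, function(e) {
    ns <- length(e$shortening); nl <- length(e$lengthening)
    if (ns == 0L && nl == 0L) NA_real_ else ns / nl
  }, numeric(1))
  structure(list(calls = rk$calls, events = events, ratio = ratio,
                 entropy = rk$table),
            class = "apa_specific_events")
}

#' Pearson pattern correlation and average-linkage clustering of clusters
#'
#' @param mat units x clusters index matrix; rows with missing values are
#'   handled pairwise. Zero-variance columns yield NA correlations and are
#'   excluded from the dendrogram.
#' @return list with `correlation` (clusters x clusters matrix, unit
#'   diagonal), `order` (dendrogram leaf order of the clusterable columns)
#'   and `hclust` (the average-linkage tree, or NULL with < 3 usable columns).
#' @export
pattern_correlation <- function(mat) {
  stopifnot(ncol(mat) >= 2L)
  r <- suppressWarnings(cor(mat, use = "pairwise.complete.obs",
                            method = "pearson"))
  diag(r) <- 1
  usable <- colnames(r)[colSums(is.na(r)) == 0L]
  hc <- NULL
  ord <- usable
  if (length(usable) >= 3L) {
    hc <- hclust(as.dist(1 - r[usable, usable]), method = "average")
    ord <- usable[hc$order]
  }
  list(correlation = r, order = ord, hclust = hc)
}
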