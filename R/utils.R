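#' @import data.table
#' @importFrom stats rpois rnorm runif median var sd setNames ks.test t.test
#'   kruskal.test pchisq cor hclust as.dist complete.cases
NULL

# internal coordinate convention: 0-based half-open everywhere; BED written as-is,
# GTF converted to/from 1-based inclusive at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Plain-character helper used by the simulator and the filter/motif scanners,
#' which operate on sense-strand sequence extracted from the reference.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtN", "TGCAtgcaN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Extract sense-strand sequence around a site. `rel_from`/`rel_to` are inclusive
# sense offsets relative to `site` (negative = upstream of the site in
# transcription direction). Returns list(seq, rel_from, rel_to) after clipping
# to chromosome bounds; seq is "" when the window is empty.
sense_window <- function(genome, chrom, strand, site, rel_from, rel_to) {
  stopifnot(rel_from <= rel_to)
  len <- nchar(genome[[chrom]])
  if (strand == "+") {
    g0 <- site + rel_from; g1 <- site + rel_to
  } else {
    g0 <- site - rel_to; g1 <- site - rel_from
  }
  g0c <- max(g0, 0L); g1c <- min(g1, len - 1L)
  if (g0c > g1c) return(list(seq = "", rel_from = rel_from, rel_to = rel_to))
  s <- substr(genome[[chrom]], g0c + 1L, g1c + 1L)
  if (strand == "-") s <- revcomp(s)
  # recompute the clipped relative window on the sense axis
  if (strand == "+") {
    rf <- g0c - site; rt <- g1c - site
  } else {
    rf <- site - g1c; rt <- site - g0c
  }
  list(seq = s, rel_from = rf, rel_to = rt)
}

# Overwrite genome sequence with `motif` given on the sense strand, starting at
# sense offset `rel_start` from `site`. Returns the modified genome.
plant_sense <- function(genome, chrom, strand, site, rel_start, motif) {
  L <- nchar(motif)
  if (strand == "+") {
    g0 <- site + rel_start
    substr(genome[[chrom]], g0 + 1L, g0 + L) <- motif
  } else {
    g0 <- site - rel_start - L + 1L
    substr(genome[[chrom]], g0 + 1L, g0 + L) <- revcomp(motif)
  }
  genome
}

# Replace the single base at sense offset `rel` from `site` (sense alphabet).
set_sense_base <- function(genome, chrom, strand, site, rel, base) {
  if (strand == "+") {
    g0 <- site + rel
    substr(genome[[chrom]], g0 + 1L, g0 + 1L) <- base
  } else {
    g0 <- site - rel
    substr(genome[[chrom]], g0 + 1L, g0 + 1L) <- revcomp(base)
  }
  genome
}

# Runs of a single character in a string: data.table(start (1-based), len).
char_runs <- function(s, ch) {
  if (nchar(s) == 0L) return(data.table(start = integer(0), len = integer(0)))
  v <- strsplit(s, "", fixed = TRUE)[[1]] == ch
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.table(start = starts[r$values], len = r$lengths[r$values])
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits; used for the
# provenance header so reruns with an identical config are recognizable.
# Arithmetic kept exact in doubles (< 2^53) by splitting into 16-bit halves.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(as.integer(h %% 65536), bitwAnd(as.integer(b), 255L))
    h <- (h %/% 65536) * 65536 + lo
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a TSV table with a provenance header
#'
#' Output files carry `#`-prefixed header lines (package version, config hash,
#' seed) so that a result can be traced back to the run that produced it.
#'
#' @param x data.frame/data.table.
#' @param path output path.
#' @param provenance named character vector added as `# key: value` lines.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(package = paste0("apadyn ", as.character(utils::packageVersion("apadyn"))),
            provenance)
  writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#'
#' @param path input path.
#' @return data.table (provenance lines are attached as attribute `provenance`).
#' @export
read_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  body <- if (length(hdr)) lines[-hdr] else lines
  dt <- fread(text = paste(body, collapse = "\n"), sep = "\t", na.strings = "NA")
  setattr(dt, "provenance", if (length(hdr)) sub("^# ", "", lines[hdr]) else character(0))
  dt
}
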