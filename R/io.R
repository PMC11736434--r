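# Format adapters. Internal convention is 0-based half-open; BED is written
# verbatim, GTF is converted to/from 1-based inclusive at the boundary.

#' Write a genome to FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write 3'-tag records as BED6
#'
#' One record per tag; `chromStart` is the 0-based 3'-end position, the name
#' field carries `barcode:cluster`, score is 0.
#'
#' @param tags tag data.table (`chrom`, `pos3`, `strand`, `barcode`, `cluster`).
#' @param path output BED path.
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.table(chrom = tags$chrom, start = tags$pos3, end = tags$pos3 + 1L,
                    name = paste0(tags$barcode, ":", tags$cluster),
                    score = 0L, strand = tags$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read 3'-tag records from BED6
#'
#' @param path BED path written by [write_tags_bed()] (name = `barcode:cluster`).
#' @return tag data.table sorted by chrom, pos3.
#' @export
read_tags_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- as.character(gr$name)
  parts <- tstrsplit(nm, ":", fixed = TRUE)
  if (length(parts) != 2L)
    stop("tag BED name field must be 'barcode:cluster'", call. = FALSE)
  tags <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                     pos3 = GenomicRanges::start(gr) - 1L,
                     strand = as.character(GenomicRanges::strand(gr)),
                     barcode = parts[[1]], cluster = parts[[2]])
  setorder(tags, chrom, pos3)
  tags[]
}

#' Write gene annotation as GTF
#'
#' Emits one feature line per annotated interval with the region class
#' (`utr3`/`intron`) in the feature column and `gene_id` in the attributes.
#'
#' @param annotation data.table (`chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `region_class`), 0-based half-open.
#' @param path output GTF path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  lines <- sprintf('%s\tapadyn\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   annotation$chrom, annotation$region_class,
                   annotation$start + 1L, annotation$end, annotation$strand,
                   annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from GTF or BED
#'
#' GTF: the feature (type) column must be `utr3`/`three_prime_utr` or `intron`
#' and records must carry a `gene_id` attribute. BED: the name field must be
#' `gene_id:region_class`.
#'
#' @param path annotation path (`.gtf`/`.gff` or `.bed`).
#' @return data.table (`chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `region_class`), 0-based half-open.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    parts <- tstrsplit(as.character(gr$name), ":", fixed = TRUE)
    ann <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      gene_id = parts[[1]], region_class = parts[[2]])
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    type <- as.character(gr$type)
    type[type == "three_prime_utr"] <- "utr3"
    ann <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      gene_id = as.character(gr$gene_id), region_class = type)
  }
  ann <- ann[region_class %in% c("utr3", "intron")]
  if (nrow(ann) == 0L)
    stop("annotation contains no utr3/intron intervals", call. = FALSE)
  ann[]
}

#' Read a known-PAS BED file for benchmarking
#'
#' Each record marks one known site; the site coordinate taken is the 0-based
#' strand-aware 3' base (`end - 1` on `+`, `start` on `-`).
#'
#' @param path BED path.
#' @return data.table (`chrom`, `pos`, `strand`).
#' @export
read_known_pas_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(GenomicRanges::strand(gr))
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = ifelse(st == "-", GenomicRanges::start(gr) - 1L,
                          GenomicRanges::end(gr) - 1L),
             strand = st)
}

#' Write all simulator outputs to a directory
#'
#' Emits `genome.fa`, `annotation.gtf`, `tags.bed`, and the truth tables
#' (`truth_pas.tsv`, `truth_usage.tsv`, `truth_genes.tsv`).
#'
#' @param reference an `apa_reference`.
#' @param tags tag table from [simulate_tags()].
#' @param outdir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_sim_outputs <- function(reference, tags, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(config = fnv1a32(config_json(reference$config)),
            seed = as.character(reference$config$seed))
  write_genome_fasta(reference$genome, file.path(outdir, "genome.fa"))
  write_annotation_gtf(reference$annotation, file.path(outdir, "annotation.gtf"))
  write_tags_bed(tags, file.path(outdir, "tags.bed"))
  write_tsv(reference$truth$pas, file.path(outdir, "truth_pas.tsv"), prov)
  write_tsv(reference$truth$usage, file.path(outdir, "truth_usage.tsv"), prov)
  write_tsv(reference$truth$genes, file.path(outdir, "truth_genes.tsv"), prov)
  invisible(outdir)
}

# canonical JSON serialization of a config (used for hashing and round-trips)
config_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
}
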