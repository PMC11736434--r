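# Synthetic 3'-tag world: a toy genome with genes carrying 1-3 3'UTR PASs,
# optional intronic PASs and planted internal-priming artifacts, plus per-cell
# tag sampling with positional jitter. Everything downstream of the aligner is
# emulated; everything upstream (library prep, mapping) is out of scope.

# fixed gene architecture, in sense offsets from the gene 5' end:
#   exon1 [0,300) | intron [300,1300) | exon2 [1300,1600) | utr3 [1600,1600+L)
SIM_EXON1 <- 300L
SIM_INTRON_LEN <- 1000L
SIM_EXON2 <- 300L
SIM_INTRON_SITE <- 800L          # intronic cleavage site (sense offset)
SIM_FIRST_PAS <- 150L            # first 3'UTR PAS, offset into the UTR
SIM_ARTIFACT_FROM_END <- 100L    # artifact site, offset from the UTR 3' end
SIM_GENE_SLOT <- 4000L
SIM_GENES_PER_CHROM <- 16L

#' Simulation configuration
#'
#' Defines the generative world: cluster ordering (a differentiation path),
#' per-gene PAS architecture, per-cluster usage proportions with planted
#' proximal-usage shifts, poly(A)-signal planting, A-rich internal-priming
#' artifact loci, and per-cell tag sampling.
#'
#' @param n_genes number of genes.
#' @param n_clusters number of cell clusters along the differentiation path.
#' @param cluster_ordering ordered cluster labels (position 1 = most primitive).
#' @param cells_per_cluster cells per cluster.
#' @param mean_tags_per_cell_per_gene Poisson mean of tags per cell per gene.
#' @param pas_per_utr probability vector over one, two or three 3'UTR PASs per gene (positional).
#' @param frac_shift_genes fraction of genes with a planted proximal-usage shift
#'   (such genes always get >= 2 3'UTR PASs).
#' @param shift_delta total increase in proximal usage from the first to the
#'   last cluster of the ordering, applied as a linear ramp.
#' @param baseline_proximal proximal usage in the first cluster (and in every
#'   cluster for stable genes).
#' @param intron_pas_prob probability that a gene carries one intronic PAS.
#' @param intron_share fraction of a gene's tags routed to its intronic PAS.
#' @param artifact_rate fraction of genes receiving a planted A-rich
#'   internal-priming artifact locus in their 3'UTR.
#' @param artifact_tag_mean Poisson mean of artifact tags per cell for genes
#'   with an artifact locus.
#' @param signal_offset nt upstream of each true cleavage site at which the
#'   planted AATAAA signal ends.
#' @param signal_prob fraction of true PASs that receive an AATAAA plant.
#' @param jitter_sd Gaussian positional jitter (nt, sd) added to tag 3' ends.
#' @param utr_length 3'UTR length (nt).
#' @param pas_spacing spacing between adjacent 3'UTR PASs (nt, >= 150).
#' @param seed integer seed; fully determines all outputs.
#' @return an object of class `apa_sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 60L,
                       n_clusters = 4L,
                       cluster_ordering = paste0("C", seq_len(n_clusters)),
                       cells_per_cluster = 100L,
                       mean_tags_per_cell_per_gene = 2,
                       pas_per_utr = c(0.2, 0.6, 0.2),
                       frac_shift_genes = 0.5,
                       shift_delta = 0.4,
                       baseline_proximal = 0.3,
                       intron_pas_prob = 0.25,
                       intron_share = 0.2,
                       artifact_rate = 0.15,
                       artifact_tag_mean = mean_tags_per_cell_per_gene,
                       signal_offset = 21L,
                       signal_prob = 1,
                       jitter_sd = 5,
                       utr_length = 900L,
                       pas_spacing = 200L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_clusters = as.integer(n_clusters),
              cluster_ordering = as.character(cluster_ordering),
              cells_per_cluster = as.integer(cells_per_cluster),
              mean_tags_per_cell_per_gene = mean_tags_per_cell_per_gene,
              pas_per_utr = unname(pas_per_utr),
              frac_shift_genes = frac_shift_genes, shift_delta = shift_delta,
              baseline_proximal = baseline_proximal,
              intron_pas_prob = intron_pas_prob, intron_share = intron_share,
              artifact_rate = artifact_rate, artifact_tag_mean = artifact_tag_mean,
              signal_offset = as.integer(signal_offset), signal_prob = signal_prob,
              jitter_sd = jitter_sd, utr_length = as.integer(utr_length),
              pas_spacing = as.integer(pas_spacing), seed = as.integer(seed))
  class(cfg) <- "apa_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c("frac_shift_genes", "shift_delta", "baseline_proximal",
          "intron_pas_prob", "intron_share", "artifact_rate", "signal_prob")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("sim_config: '", f, "' must lie in [0,1]", call. = FALSE)
  }
  if (cfg$baseline_proximal + cfg$shift_delta > 1)
    stop("sim_config: baseline_proximal + shift_delta must be <= 1", call. = FALSE)
  if (length(cfg$pas_per_utr) != 3L || abs(sum(cfg$pas_per_utr) - 1) > 1e-8 ||
      any(cfg$pas_per_utr < 0))
    stop("sim_config: pas_per_utr must be a probability vector over 1..3 PASs",
         call. = FALSE)
  if (cfg$pas_spacing < 150L)
    stop("sim_config: pas_spacing must be >= 150 nt", call. = FALSE)
  kmax <- max(which(cfg$pas_per_utr > 0))
  if (cfg$frac_shift_genes > 0) kmax <- max(kmax, 2L)
  # last PAS needs >= 250 nt of clearance before the artifact locus so that
  # artifact A-runs never enter a true peak's filter window
  last_pas <- SIM_FIRST_PAS + cfg$pas_spacing * (kmax - 1L)
  if (last_pas + 250L > cfg$utr_length - SIM_ARTIFACT_FROM_END)
    stop("sim_config: utr_length too short for ", kmax, " PASs spaced ",
         cfg$pas_spacing, " nt apart", call. = FALSE)
  if (cfg$n_clusters != length(cfg$cluster_ordering))
    stop("sim_config: cluster_ordering length must equal n_clusters", call. = FALSE)
  if (cfg$jitter_sd < 0 || cfg$mean_tags_per_cell_per_gene <= 0)
    stop("sim_config: invalid jitter_sd or mean_tags_per_cell_per_gene", call. = FALSE)
  invisible(cfg)
}

# gene body length for a config
sim_gene_len <- function(cfg) SIM_EXON1 + SIM_INTRON_LEN + SIM_EXON2 + cfg$utr_length

#' Generate the reference world: genome, annotation and ground truth
#'
#' Lays genes out on toy chromosomes (half on each strand), draws the per-gene
#' PAS architecture, plants AATAAA signals ending `signal_offset` nt upstream
#' of each true cleavage site, plants A-rich runs 10-140 nt downstream of
#' artifact loci, scrubs accidental A-runs from the filter windows of true
#' sites, and tabulates per-cluster usage proportions (with a linear proximal
#' ramp for shifted genes).
#'
#' @param config an [sim_config()] object.
#' @return an object of class `apa_reference`: list with `genome` (named
#'   character vector of chromosome sequences), `annotation` (data.table of
#'   0-based half-open `utr3`/`intron` intervals per gene), `truth`
#'   (class `apa_truth`: `pas`, `usage`, `genes` tables) and `config`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  glen <- sim_gene_len(cfg)
  stopifnot(glen + 1000L <= SIM_GENE_SLOT)

  n <- cfg$n_genes
  gene_id <- sprintf("g%03d", seq_len(n))
  chrom_idx <- (seq_len(n) - 1L) %/% SIM_GENES_PER_CHROM
  slot <- (seq_len(n) - 1L) %% SIM_GENES_PER_CHROM
  chrom <- sprintf("chr%d", chrom_idx + 1L)
  gstart <- slot * SIM_GENE_SLOT + 500L
  gend <- gstart + glen
  strand <- rep(c("+", "-"), length.out = n)

  # random genome
  chroms <- unique(chrom)
  genome <- vapply(chroms, function(cc) {
    ng <- sum(chrom == cc)
    L <- ng * SIM_GENE_SLOT + 1000L
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))

  # gene architecture draws
  k_utr <- sample(1:3, n, replace = TRUE, prob = cfg$pas_per_utr)
  n_shift <- round(cfg$frac_shift_genes * n)
  shifted_idx <- if (n_shift > 0) sample.int(n, n_shift) else integer(0)
  shifted <- seq_len(n) %in% shifted_idx
  if (any(shifted & k_utr < 2L)) {
    p23 <- cfg$pas_per_utr[2:3]
    p23 <- if (sum(p23) > 0) p23 / sum(p23) else c(1, 0)
    idx <- which(shifted & k_utr < 2L)
    k_utr[idx] <- sample(2:3, length(idx), replace = TRUE, prob = p23)
  }
  has_intron <- runif(n) < cfg$intron_pas_prob
  n_art <- round(cfg$artifact_rate * n)
  art_idx <- if (n_art > 0) sample.int(n, n_art) else integer(0)
  has_artifact <- seq_len(n) %in% art_idx

  s2g <- function(i, off) if (strand[i] == "+") gstart[i] + off else gend[i] - 1L - off
  iv2g <- function(i, a, b) {  # sense [a,b) -> genomic half-open
    if (strand[i] == "+") c(gstart[i] + a, gstart[i] + b)
    else c(gend[i] - b, gend[i] - a)
  }

  utr_a <- SIM_EXON1 + SIM_INTRON_LEN + SIM_EXON2          # sense start of utr3
  ann_list <- vector("list", n)
  pas_list <- vector("list", n)
  for (i in seq_len(n)) {
    iv_u <- iv2g(i, utr_a, utr_a + cfg$utr_length)
    iv_i <- iv2g(i, SIM_EXON1, SIM_EXON1 + SIM_INTRON_LEN)
    ann_list[[i]] <- data.table(
      chrom = chrom[i], start = c(iv_u[1], iv_i[1]), end = c(iv_u[2], iv_i[2]),
      strand = strand[i], gene_id = gene_id[i],
      region_class = c("utr3", "intron"))
    offs <- utr_a + SIM_FIRST_PAS + cfg$pas_spacing * (seq_len(k_utr[i]) - 1L)
    pas <- data.table(gene_id = gene_id[i],
                      pas_id = sprintf("%s:utr%d", gene_id[i], seq_len(k_utr[i])),
                      chrom = chrom[i], strand = strand[i], region_class = "utr3",
                      site = vapply(offs, function(o) s2g(i, o), numeric(1)),
                      kind = "true_pas", utr_rank = seq_len(k_utr[i]))
    if (has_intron[i]) {
      pas <- rbind(pas, data.table(
        gene_id = gene_id[i], pas_id = paste0(gene_id[i], ":int1"),
        chrom = chrom[i], strand = strand[i], region_class = "intron",
        site = s2g(i, SIM_EXON1 + SIM_INTRON_SITE), kind = "true_pas",
        utr_rank = NA_integer_))
    }
    if (has_artifact[i]) {
      pas <- rbind(pas, data.table(
        gene_id = gene_id[i], pas_id = paste0(gene_id[i], ":art1"),
        chrom = chrom[i], strand = strand[i], region_class = "utr3",
        site = s2g(i, utr_a + cfg$utr_length - SIM_ARTIFACT_FROM_END),
        kind = "artifact", utr_rank = NA_integer_))
    }
    pas_list[[i]] <- pas
  }
  annotation <- rbindlist(ann_list)
  pas <- rbindlist(pas_list)
  pas[, site := as.integer(site)]

  # plant poly(A) signals (true PASs only), then artifact A-runs, then scrub
  pas[, signal := FALSE]
  truep <- which(pas$kind == "true_pas")
  planted <- truep[runif(length(truep)) < cfg$signal_prob]
  pas$signal[planted] <- TRUE
  for (j in planted) {
    genome <- plant_sense(genome, pas$chrom[j], pas$strand[j], pas$site[j],
                          -(cfg$signal_offset + 5L), "AATAAA")
  }
  for (j in which(pas$kind == "artifact")) {
    genome <- plant_sense(genome, pas$chrom[j], pas$strand[j], pas$site[j],
                          20L, strrep("A", 10L))
  }
  # remove accidental sense A-runs (>=7 nt) within 1..230 nt downstream of every
  # true cleavage site so the internal-priming filters cannot hit true peaks
  for (j in truep) {
    w <- sense_window(genome, pas$chrom[j], pas$strand[j], pas$site[j], 1L, 230L)
    runs <- char_runs(w$seq, "A")
    runs <- runs[len >= 7L]
    for (r in seq_len(nrow(runs))) {
      rel <- w$rel_from + runs$start[r] - 1L + 3L  # break the run at its 4th base
      genome <- set_sense_base(genome, pas$chrom[j], pas$strand[j], pas$site[j],
                               rel, "C")
    }
  }

  # per-cluster usage proportions over each gene's true PASs (sum to 1)
  m <- cfg$n_clusters
  ramp <- if (m > 1) (seq_len(m) - 1) / (m - 1) else 0
  usage_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gene_id[i]
    gp <- pas[gene_id == g & kind == "true_pas"]
    ish <- if (has_intron[i]) cfg$intron_share else 0
    k <- k_utr[i]
    prox <- if (shifted[i] && k >= 2L) {
      cfg$baseline_proximal + cfg$shift_delta * ramp
    } else if (k >= 2L) rep(cfg$baseline_proximal, m) else rep(1, m)
    rows <- lapply(seq_len(m), function(ci) {
      pu <- numeric(k)
      if (k == 1L) pu[1] <- 1 else {
        pu[1] <- prox[ci]
        pu[-1] <- (1 - prox[ci]) / (k - 1)
      }
      props <- c(pu * (1 - ish), if (has_intron[i]) ish)
      data.table(gene_id = g, pas_id = gp$pas_id,
                 cluster = cfg$cluster_ordering[ci], prop = props)
    })
    usage_list[[i]] <- rbindlist(rows)
  }
  usage <- rbindlist(usage_list)

  genes <- data.table(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = gstart, end = gend, shifted = shifted,
                      n_utr_pas = k_utr, has_intron_pas = has_intron,
                      has_artifact = has_artifact)
  truth <- structure(list(pas = pas, usage = usage, genes = genes),
                     class = "apa_truth")
  structure(list(genome = genome, annotation = annotation, truth = truth,
                 config = cfg), class = "apa_reference")
}

#' Cell barcodes and their cluster labels for a configuration
#'
#' @param config an [sim_config()] object.
#' @return data.table with columns `barcode`, `cluster`.
#' @export
sim_barcodes <- function(config) {
  data.table(
    barcode = paste0(rep(config$cluster_ordering, each = config$cells_per_cluster),
                     "_cell", sprintf("%03d", seq_len(config$cells_per_cluster))),
    cluster = rep(config$cluster_ordering, each = config$cells_per_cluster))
}

#' Simulate 3'-tag records from a reference world
#'
#' Per cell and gene the tag count is Poisson with the configured mean; each
#' tag's PAS is drawn from the gene-by-cluster truth proportions; the recorded
#' 3'-end position is the cleavage site plus rounded Gaussian jitter. Artifact
#' loci additionally emit tags at `artifact_tag_mean` per cell.
#'
#' @param reference an `apa_reference` from [generate_reference()].
#' @param config optional config override (defaults to the reference's).
#' @return data.table of tag records sorted by chrom, pos3 with columns
#'   `chrom`, `pos3` (0-based 3'-most aligned base), `strand`, `barcode`,
#'   `cluster`; barcode/cluster map attached as attribute `barcodes`.
#' @export
simulate_tags <- function(reference, config = reference$config) {
  cfg <- config
  if (nrow(reference$annotation) == 0L) stop("empty annotation", call. = FALSE)
  set.seed(cfg$seed + 1L)
  bc <- sim_barcodes(cfg)
  pas <- reference$truth$pas
  usage <- reference$truth$usage
  genes <- reference$truth$genes
  chrom_len <- nchar(reference$genome)

  out <- vector("list", nrow(genes) * cfg$n_clusters)
  idx <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    gp <- pas[gene_id == g & kind == "true_pas"]
    art <- pas[gene_id == g & kind == "artifact"]
    for (cl in cfg$cluster_ordering) {
      cells <- bc[cluster == cl, barcode]
      counts <- rpois(length(cells), cfg$mean_tags_per_cell_per_gene)
      tot <- sum(counts)
      props <- usage[gene_id == g & cluster == cl][match(gp$pas_id, pas_id), prop]
      picked <- if (tot > 0) sample.int(nrow(gp), tot, replace = TRUE, prob = props)
                else integer(0)
      pos <- gp$site[picked]
      bcs <- rep(cells, counts)
      if (nrow(art) == 1L && genes$has_artifact[i]) {
        acounts <- rpois(length(cells), cfg$artifact_tag_mean)
        pos <- c(pos, rep(art$site, sum(acounts)))
        bcs <- c(bcs, rep(cells, acounts))
      }
      ntag <- length(pos)
      if (ntag == 0L) next
      if (cfg$jitter_sd > 0) pos <- pos + as.integer(round(rnorm(ntag, 0, cfg$jitter_sd)))
      pos <- pmin(pmax(pos, 0L), chrom_len[[genes$chrom[i]]] - 1L)
      idx <- idx + 1L
      out[[idx]] <- data.table(chrom = genes$chrom[i], pos3 = as.integer(pos),
                               strand = genes$strand[i], barcode = bcs,
                               cluster = cl)
    }
  }
  tags <- rbindlist(out[seq_len(idx)])
  setorder(tags, chrom, pos3)
  setattr(tags, "barcodes", bc)
  tags[]
}
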