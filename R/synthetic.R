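#' Configuration for the synthetic developmental ATAC/RNA study
#'
#' Defines a seeded, desk-scale emulation of a three-stage, four-
#' replicate chromatin accessibility + expression study: a small
#' multi-chromosome genome laid out in fixed gene slots, stage-common
#' and stage-specific peaks (a configurable fraction planted in
#' proximal promoters), partially reproducible replicate peak calls
#' with end jitter and per-replicate irreproducible noise peaks,
#' negative-binomial counts with planted fold changes for the
#' differential-peak-intensity stage, gene expression with six planted
#' temporal archetype profiles and a planted promoter-ACR-length vs
#' expression trend, and a motif planted in a fraction of
#' stage-specific peak windows.
#'
#' @param seed Integer seed; fixes every emitted byte.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_genes Number of genes (each 2 kb, two 500 bp exons, placed
#'   in 5 kb slots).
#' @param stages Stage labels, in developmental order.
#' @param replicates_per_stage Replicates per stage.
#' @param n_common_peaks Peaks shared by all stages.
#' @param n_specific_peaks Per-stage specific peak counts (recycled).
#' @param promoter_peak_fraction Fraction of truth peaks centered in
#'   proximal promoter windows.
#' @param peak_width_range Min/max truth peak width (bp).
#' @param replicate_reproducibility Probability a truth peak appears in
#'   a given replicate.
#' @param jitter_bp Maximum +/- jitter on each replicate peak end.
#' @param n_noise_peaks Irreproducible random peaks added per
#'   replicate.
#' @param nb_mean,nb_dispersion Negative-binomial baseline for peak
#'   counts.
#' @param dpi_lfc Planted log2 fold change magnitude for DPI peaks.
#' @param n_dpi_up,n_dpi_down Common peaks opened/closed at the last
#'   stage.
#' @param n_dpi_mid Common peaks opened at the middle stage.
#' @param deg_archetypes 6 x n_stages matrix of log2 expression
#'   offsets, one row per temporal cluster shape.
#' @param n_deg_per_cluster Genes planted per archetype.
#' @param gene_nb_dispersion Dispersion for gene counts.
#' @param library_size Nominal per-sample mapped fragments (for FPKM).
#' @param library_log2_jitter Per-sample depth jitter (log2 half-range).
#' @param motif_consensus Planted motif consensus sequence.
#' @param motif_plant_rate Fraction of target windows carrying the
#'   motif.
#' @param motif_target_stage Stage whose specific peaks are the motif
#'   targets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    chrom_lengths = c(chr1 = 800000L, chr2 = 600000L,
                      chr3 = 400000L, chr4 = 200000L),
    n_genes = 180L,
    stages = c("S1", "S2", "S3"),
    replicates_per_stage = 4L,
    n_common_peaks = 240L,
    n_specific_peaks = c(60L, 60L, 60L),
    promoter_peak_fraction = 0.4,
    peak_width_range = c(200L, 600L),
    replicate_reproducibility = 1.0,
    jitter_bp = 20L,
    n_noise_peaks = 50L,
    nb_mean = 100,
    nb_dispersion = 0.05,
    dpi_lfc = 2,
    n_dpi_up = 20L, n_dpi_down = 20L, n_dpi_mid = 20L,
    deg_archetypes = rbind(
      c(0, 0, 3),      # low, low, sharp increase at the last stage
      c(0, 1.5, 3),    # steady increase
      c(3, 1.5, 0),    # steady decrease
      c(3, 0, 0),      # sharp decrease after the first stage
      c(0, 3, 0),      # transient peak at the middle stage
      c(3, 0, 1.5)),   # highest first, lowest middle, partial rebound
    n_deg_per_cluster = 10L,
    gene_nb_dispersion = 0.05,
    library_size = 2e7,
    library_log2_jitter = 0.3,
    motif_consensus = "TGACGTCA",
    motif_plant_rate = 0.5,
    motif_target_stage = "S1") {
  cfg <- as.list(environment())
  stopifnot(all(cfg$chrom_lengths > 0),
            cfg$promoter_peak_fraction >= 0,
            cfg$promoter_peak_fraction <= 1,
            cfg$replicate_reproducibility >= 0,
            cfg$replicate_reproducibility <= 1,
            nrow(cfg$deg_archetypes) == 6L,
            ncol(cfg$deg_archetypes) == length(cfg$stages))
  cfg$n_specific_peaks <- setNames(
    rep(cfg$n_specific_peaks, length.out = length(stages)), stages)
  structure(cfg, class = "synthetic_config")
}

slot_bp <- 5000L
gene_body_bp <- 2000L

# deterministic gene/slot layout: 5 kb slots per chromosome; a gene
# slot holds a 2 kb gene whose promoter window stays inside the slot
synthetic_layout <- function(cfg) {
  slots <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
    n <- cfg$chrom_lengths[[ch]] %/% slot_bp
    data.frame(chrom = ch, slot_start = slot_bp * (seq_len(n) - 1L) + 1L)
  }))
  if (cfg$n_genes > nrow(slots))
    stop("infeasible config: more genes than genome slots")
  gene_rows <- sort(sample(nrow(slots), cfg$n_genes))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  s0 <- slots$slot_start[gene_rows]
  body_start <- ifelse(strand == "+", s0 + 2500L, s0 + 500L)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = slots$chrom[gene_rows],
    start = body_start, end = body_start + gene_body_bp - 1L,
    strand = strand,
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end)
  empty <- slots[-gene_rows, , drop = FALSE]
  list(slots = slots, genes = genes, empty_slots = empty)
}

# candidate peak sites: one proximal-promoter site per chosen gene,
# two intergenic anchors per empty slot (2.5 kb apart, so truth peaks
# of width <= 600 never collide)
synthetic_peak_sites <- function(cfg, layout) {
  total <- cfg$n_common_peaks + sum(cfg$n_specific_peaks)
  n_prom <- round(cfg$promoter_peak_fraction * total)
  n_inter <- total - n_prom
  if (n_prom > nrow(layout$genes))
    stop("infeasible config: more promoter peaks than genes")
  if (n_inter > 2L * nrow(layout$empty_slots))
    stop("infeasible config: more intergenic peaks than free anchors")
  widths <- sample(seq(cfg$peak_width_range[1L],
                       cfg$peak_width_range[2L]), total, replace = TRUE)
  widths <- widths - widths %% 2L  # even widths keep windows centered
  prom_genes <- layout$genes[sample(nrow(layout$genes), n_prom), ,
                             drop = FALSE]
  # center in the proximal window: -700..0 of the TSS in gene
  # orientation keeps the midpoint inside -1000..+100 for all widths
  off <- sample(0:700, n_prom, replace = TRUE)
  center_p <- ifelse(prom_genes$strand == "+",
                     prom_genes$tss - off, prom_genes$tss + off)
  empt <- layout$empty_slots[
    sample(nrow(layout$empty_slots), ceiling(n_inter / 2)), ,
    drop = FALSE]
  anchors <- data.frame(
    chrom = rep(empt$chrom, each = 2L),
    center = as.vector(rbind(empt$slot_start + 1250L,
                             empt$slot_start + 3750L)))
  anchors <- anchors[seq_len(n_inter), , drop = FALSE]
  sites <- data.frame(
    chrom = c(prom_genes$chrom, anchors$chrom),
    center = as.integer(c(center_p, anchors$center)),
    gene_id = c(prom_genes$gene_id, rep(NA_character_, n_inter)),
    promoter = rep(c(TRUE, FALSE), c(n_prom, n_inter)),
    stringsAsFactors = FALSE)
  sites <- sites[sample(nrow(sites)), , drop = FALSE]
  sites$width <- widths
  sites$start <- sites$center - sites$width %/% 2L
  sites$end <- sites$start + sites$width - 1L
  sites$start <- pmax(sites$start, 1L)
  sites$end <- pmin(sites$end, cfg$chrom_lengths[sites$chrom])
  rownames(sites) <- NULL
  sites
}

#' Generate the synthetic study bundle
#'
#' Emits, under `out_dir`: `chrom.sizes`, `genome.fa`, `genes.gtf`,
#' one narrowPeak file per stage x replicate under `peaks/`,
#' `peak_counts.tsv` (common-peak universe), `gene_counts.tsv`,
#' `samples.tsv` (with a library_size column for FPKM),
#' `motifs.meme` and `truth.json`.  Identical seeds give byte-identical
#' bundles; all randomness flows from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `truth` (the planted-parameter record, also written as JSON).
#' @export
generate_synthetic_study <- function(config, out_dir) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)

  layout <- synthetic_layout(cfg)
  sites <- synthetic_peak_sites(cfg, layout)
  n_common <- cfg$n_common_peaks
  cat_stage <- c(rep("common", n_common),
                 rep(names(cfg$n_specific_peaks), cfg$n_specific_peaks))
  ids <- character(nrow(sites))
  ids[cat_stage == "common"] <- sprintf("common_%04d", seq_len(n_common))
  for (s in cfg$stages)
    ids[cat_stage == s] <- sprintf("%s_specific_%04d", s,
                                   seq_len(sum(cat_stage == s)))
  peaks_truth <- cbind(sites, data.frame(id = ids, category = cat_stage,
                                         stringsAsFactors = FALSE))

  # ---- replicate narrowPeak files -------------------------------------
  sample_sheet <- expand.grid(replicate = seq_len(cfg$replicates_per_stage),
                              stage = cfg$stages, stringsAsFactors = FALSE)
  sample_sheet <- sample_sheet[, c("stage", "replicate")]
  sample_sheet$sample_id <- sprintf("%s_rep%d", sample_sheet$stage,
                                    sample_sheet$replicate)
  peak_paths <- character(nrow(sample_sheet))
  for (i in seq_len(nrow(sample_sheet))) {
    st <- sample_sheet$stage[i]
    tr <- peaks_truth[peaks_truth$category %in% c("common", st), ,
                      drop = FALSE]
    keep <- runif(nrow(tr)) <= cfg$replicate_reproducibility
    tr <- tr[keep, , drop = FALSE]
    j <- cfg$jitter_bp
    if (j > 0 && nrow(tr) > 0) {
      tr$start <- tr$start + sample(-j:j, nrow(tr), replace = TRUE)
      tr$end <- tr$end + sample(-j:j, nrow(tr), replace = TRUE)
      tr$start <- pmax(tr$start, 1L)
      tr$end <- pmin(pmax(tr$end, tr$start + 49L),
                     cfg$chrom_lengths[tr$chrom])
    }
    if (cfg$n_noise_peaks > 0) {
      w <- sample(seq(cfg$peak_width_range[1L], cfg$peak_width_range[2L]),
                  cfg$n_noise_peaks, replace = TRUE)
      ch <- sample(names(cfg$chrom_lengths), cfg$n_noise_peaks,
                   replace = TRUE, prob = as.numeric(cfg$chrom_lengths))
      st0 <- 1L + floor(runif(cfg$n_noise_peaks) *
                          (cfg$chrom_lengths[ch] - w + 1L))
      noise <- data.frame(chrom = ch, start = as.integer(st0),
                          end = as.integer(st0 + w - 1L))
      tr <- rbind(tr[, c("chrom", "start", "end")], noise)
    } else tr <- tr[, c("chrom", "start", "end")]
    ord <- order(tr$chrom, tr$start, tr$end)
    tr <- tr[ord, , drop = FALSE]
    np <- data.frame(chrom = tr$chrom, start = tr$start - 1L,
                     end = tr$end,
                     name = sprintf("%s_peak_%05d",
                                    sample_sheet$sample_id[i],
                                    seq_len(nrow(tr))),
                     score = 0L, strand = ".",
                     signal = round(runif(nrow(tr), 2, 20), 3),
                     pscore = round(runif(nrow(tr), 3, 30), 3),
                     qscore = round(runif(nrow(tr), 2, 25), 3),
                     summit = (tr$end - tr$start + 1L) %/% 2L)
    peak_paths[i] <- file.path(out_dir, "peaks",
                               paste0(sample_sheet$sample_id[i],
                                      ".narrowPeak"))
    write.table(np, peak_paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }

  # ---- counts ---------------------------------------------------------
  counts <- plant_counts(peaks_truth, layout$genes, sample_sheet, cfg)

  # ---- genome sequence with planted motif -----------------------------
  chrseq <- lapply(cfg$chrom_lengths, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  targets <- peaks_truth[peaks_truth$category == cfg$motif_target_stage, ,
                         drop = FALSE]
  planted_sel <- runif(nrow(targets)) <= cfg$motif_plant_rate
  planted <- targets[planted_sel, , drop = FALSE]
  motif_chars <- strsplit(cfg$motif_consensus, "")[[1L]]
  for (i in seq_len(nrow(planted))) {
    mid <- planted$start[i] + (planted$end[i] - planted$start[i] + 1L) %/% 2L
    at <- mid - length(motif_chars) %/% 2L
    chrseq[[planted$chrom[i]]][at:(at + length(motif_chars) - 1L)] <-
      motif_chars
  }
  fa <- Biostrings::DNAStringSet(vapply(chrseq, paste0, "",
                                        collapse = ""))
  names(fa) <- names(cfg$chrom_lengths)
  fa_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(fa, fa_path, width = 80L)

  # ---- annotation files ----------------------------------------------
  cs_path <- file.path(out_dir, "chrom.sizes")
  write.table(data.frame(names(cfg$chrom_lengths),
                         unname(cfg$chrom_lengths)),
              cs_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  gtf_path <- file.path(out_dir, "genes.gtf")
  write_synthetic_gtf(layout$genes, gtf_path)
  meme_path <- file.path(out_dir, "motifs.meme")
  write_synthetic_meme(cfg$motif_consensus, meme_path)

  sheet_path <- file.path(out_dir, "samples.tsv")
  write.table(counts$samples, sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pc_path <- file.path(out_dir, "peak_counts.tsv")
  write.table(data.frame(feature_id = rownames(counts$peak_counts),
                         counts$peak_counts, check.names = FALSE),
              pc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gc_path <- file.path(out_dir, "gene_counts.tsv")
  write.table(data.frame(feature_id = rownames(counts$gene_counts),
                         counts$gene_counts, check.names = FALSE),
              gc_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    peaks = peaks_truth[, c("id", "chrom", "start", "end", "width",
                            "category", "promoter", "gene_id")],
    specific_ids = lapply(setNames(cfg$stages, cfg$stages), function(s)
      peaks_truth$id[peaks_truth$category == s]),
    common_ids = peaks_truth$id[peaks_truth$category == "common"],
    peak_log2_multipliers = data.frame(
      id = rownames(counts$peak_log2_mult), counts$peak_log2_mult,
      check.names = FALSE, row.names = NULL),
    promoter_map = peaks_truth[peaks_truth$promoter,
                               c("gene_id", "id", "width")],
    deg_genes = counts$deg_genes,
    gene_clusters = data.frame(gene_id = names(counts$gene_clusters),
                               cluster = unname(counts$gene_clusters)),
    motif_planted_ids = planted$id,
    motif_target_ids = targets$id,
    stages = cfg$stages,
    seed = cfg$seed)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  invisible(list(
    paths = list(chrom_sizes = cs_path, fasta = fa_path, gtf = gtf_path,
                 peaks = setNames(peak_paths, sample_sheet$sample_id),
                 peak_counts = pc_path, gene_counts = gc_path,
                 samples = sheet_path, meme = meme_path,
                 truth = truth_path),
    truth = truth, samples = counts$samples, config = cfg))
}

#' Plant negative-binomial count matrices for peaks and genes
#'
#' Peak counts cover the common-peak universe with planted stage
#' multipliers (2^dpi_lfc up/down at the last stage, up at the middle
#' stage) on designated DPI peaks.  Gene counts follow per-gene
#' baselines with the six archetype stage offsets on the planted DEGs
#' and a monotone promoter-ACR-length -> expression trend on genes
#' carrying a promoter peak.
#'
#' @param peaks_truth Truth peak table (internal layout from
#'   [generate_synthetic_study()]).
#' @param genes Gene layout table.
#' @param sample_sheet data.frame (stage, replicate, sample_id).
#' @param cfg A [synthetic_config()].
#' @return List with peak_counts, gene_counts, samples (sheet with
#'   library_size), peak_log2_mult, deg_genes, gene_clusters.
#' @export
plant_counts <- function(peaks_truth, genes, sample_sheet, cfg) {
  nst <- length(cfg$stages)
  common <- peaks_truth[peaks_truth$category == "common", , drop = FALSE]
  nC <- nrow(common)
  n_dpi <- cfg$n_dpi_up + cfg$n_dpi_down + cfg$n_dpi_mid
  if (n_dpi > nC) stop("infeasible config: more DPI peaks than common peaks")
  lmult <- matrix(0, nrow = nC, ncol = nst,
                  dimnames = list(common$id, cfg$stages))
  dpi_rows <- sample(nC, n_dpi)
  up <- dpi_rows[seq_len(cfg$n_dpi_up)]
  down <- dpi_rows[cfg$n_dpi_up + seq_len(cfg$n_dpi_down)]
  mid <- dpi_rows[cfg$n_dpi_up + cfg$n_dpi_down + seq_len(cfg$n_dpi_mid)]
  lmult[up, nst] <- cfg$dpi_lfc
  lmult[down, nst] <- -cfg$dpi_lfc
  if (nst >= 2L) lmult[mid, ceiling(nst / 2)] <- cfg$dpi_lfc

  depth <- 2^runif(nrow(sample_sheet), -cfg$library_log2_jitter,
                   cfg$library_log2_jitter)
  samples <- sample_sheet
  samples$library_size <- round(cfg$library_size * depth)
  stage_idx <- match(sample_sheet$stage, cfg$stages)

  base_peak <- cfg$nb_mean * 2^runif(nC, -1, 1)
  peak_counts <- matrix(0L, nrow = nC, ncol = nrow(sample_sheet),
                        dimnames = list(common$id, sample_sheet$sample_id))
  for (j in seq_len(nrow(sample_sheet))) {
    mu <- base_peak * 2^lmult[, stage_idx[j]] * depth[j]
    peak_counts[, j] <- rnbinom(nC, mu = mu, size = 1 / cfg$nb_dispersion)
  }

  # gene baselines: promoter-peak genes get expression scaling with
  # their planted ACR length (the length -> expression trend)
  ng <- nrow(genes)
  base_log2 <- runif(ng, 2, 12)
  prom <- peaks_truth[peaks_truth$promoter, , drop = FALSE]
  m <- match(prom$gene_id, genes$gene_id)
  pct <- rank(prom$width, ties.method = "average") / nrow(prom)
  base_log2[m] <- 2 + 9.5 * pct + stats::rnorm(nrow(prom), 0, 0.5)
  n_deg <- 6L * cfg$n_deg_per_cluster
  if (n_deg > ng) stop("infeasible config: more DEGs than genes")
  deg_rows <- sample(ng, n_deg)
  gene_clusters <- setNames(rep(seq_len(6L), each = cfg$n_deg_per_cluster),
                            genes$gene_id[deg_rows])
  base_log2[deg_rows] <- runif(n_deg, 6, 9)
  goff <- matrix(0, nrow = ng, ncol = nst)
  goff[deg_rows, ] <- cfg$deg_archetypes[
    rep(seq_len(6L), each = cfg$n_deg_per_cluster), , drop = FALSE]
  gene_counts <- matrix(0L, nrow = ng, ncol = nrow(sample_sheet),
                        dimnames = list(genes$gene_id,
                                        sample_sheet$sample_id))
  for (j in seq_len(nrow(sample_sheet))) {
    mu <- 2^(base_log2 + goff[, stage_idx[j]]) * depth[j]
    gene_counts[, j] <- rnbinom(ng, mu = mu,
                                size = 1 / cfg$gene_nb_dispersion)
  }
  list(peak_counts = peak_counts, gene_counts = gene_counts,
       samples = samples, peak_log2_mult = lmult,
       deg_genes = genes$gene_id[deg_rows],
       gene_clusters = gene_clusters)
}

write_synthetic_gtf <- function(genes, path) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attr_ <- sprintf('gene_id "%s";', g$gene_id)
    ex1 <- c(g$start, g$start + 499L)
    ex2 <- c(g$end - 499L, g$end)
    data.frame(chrom = g$chrom, source = "synthetic",
               feature = c("gene", "exon", "exon"),
               start = c(g$start, ex1[1L], ex2[1L]),
               end = c(g$end, ex1[2L], ex2[2L]),
               score = ".", strand = g$strand, frame = ".",
               attributes = attr_)
  })
  gtf <- do.call(rbind, rows)
  write.table(gtf, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# planted motif at 0.85 dominant-base probability plus an unplanted
# decoy motif, in minimal MEME format
write_synthetic_meme <- function(consensus, path,
                                 decoy = "GATAAGGA") {
  prob_block <- function(cons) {
    bases <- strsplit(cons, "")[[1L]]
    mat <- matrix(0.05, nrow = length(bases), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_along(bases)) mat[i, bases[i]] <- 0.85
    apply(mat, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " "))
  }
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (nm_cons in list(c("planted_motif", consensus),
                       c("decoy_motif", decoy))) {
    lines <- c(lines,
               paste("MOTIF", nm_cons[1L]),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nchar(nm_cons[2L])),
               prob_block(nm_cons[2L]), "")
  }
  writeLines(lines, path)
  invisible(path)
}
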