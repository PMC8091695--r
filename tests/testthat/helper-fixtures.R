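# Programmatic fixtures shared across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# write a GTF from a gene table (1-based closed coords) and read it back
# genes: data.frame(gene_id, chrom, strand, exon_starts, exon_ends as
# list-columns)
write_test_gtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- g$exon_starts[[1L]]; ee <- g$exon_ends[[1L]]
    attr_ <- sprintf('gene_id "%s";', g$gene_id)
    lines <- c(lines,
               paste(g$chrom, "test", "gene", min(es), max(ee), ".",
                     g$strand, ".", attr_, sep = "\t"),
               vapply(seq_along(es), function(k)
                 paste(g$chrom, "test", "exon", es[k], ee[k], ".",
                       g$strand, ".", attr_, sep = "\t"), ""))
  }
  writeLines(lines, path)
  path
}

gene_row <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             exon_starts = I(list(exon_starts)),
             exon_ends = I(list(exon_ends)),
             stringsAsFactors = FALSE)
}

# models on one 1 Mb chromosome with a single + gene (tss 5001 1-based,
# i.e. position 5000 in 0-based coords) and a single - gene
simple_models <- function() {
  cs <- c(chrA = 1000000L)
  gtab <- rbind(
    gene_row("gPlus", "chrA", "+", c(5001, 6001), c(5500, 7000)),
    gene_row("gMinus", "chrA", "-", c(50001, 52001), c(50500, 53000)))
  read_gene_models(write_test_gtf(gtab), cs)
}

# write peak lines (0-based half-open) in a dialect
write_peak_file <- function(df, dialect = "BED3",
                            path = tempfile(fileext = ".bed")) {
  rows <- apply(df, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(rows, path)
  path
}

gr1 <- function(starts, ends, chrom = "chrA", seqlen = NULL) {
  # 1-based closed convenience constructor
  g <- GRanges(chrom, IRanges(starts, ends))
  if (!is.null(seqlen)) {
    seqlevels(g) <- names(seqlen); seqlengths(g) <- unname(seqlen)
  }
  g
}

# ---- per-base brute-force oracles (independent of the package's
# interval code: everything is done on position masks) ----------------

mask_of <- function(gr, len) {
  m <- rep(FALSE, len)
  for (i in seq_along(gr)) m[start(gr)[i]:end(gr)[i]] <- TRUE
  m
}

runs_to_granges <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep))
    return(GRanges(seqnames = factor(character(), levels = chrom),
                   ranges = IRanges()))
  GRanges(chrom, IRanges(starts[keep], ends[keep]))
}

oracle_consensus <- function(rep_sets, len, chrom = "chrA") {
  m <- Reduce(`&`, lapply(rep_sets, mask_of, len = len))
  runs_to_granges(m, chrom)
}

oracle_coverage <- function(gr, len) {
  if (length(gr) == 0L) return(0)
  mean(mask_of(gr, len))
}

oracle_partition <- function(stage_sets, len) {
  masks <- lapply(stage_sets, mask_of, len = len)
  stages <- names(stage_sets)
  specific <- lapply(stages, function(s) {
    other <- Reduce(`|`, masks[setdiff(stages, s)])
    keep <- vapply(seq_along(stage_sets[[s]]), function(i) {
      pos <- start(stage_sets[[s]])[i]:end(stage_sets[[s]])[i]
      !any(other[pos])
    }, logical(1))
    stage_sets[[s]][keep]
  })
  names(specific) <- stages
  ref <- stage_sets[[1L]]
  keep <- vapply(seq_along(ref), function(i) {
    pos <- start(ref)[i]:end(ref)[i]
    all(vapply(masks[-1L], function(m) any(m[pos]), logical(1)))
  }, logical(1))
  list(specific = specific, common = ref[keep])
}

# label every base of a toy genome with the five feature classes using
# direct loops over the gene table, then read off interval midpoints
oracle_classify <- function(gr, models,
                            prom_up = 2000, prom_dn = 100,
                            tts_up = 100, tts_dn = 1000) {
  genes <- models$genes
  cs <- models$chrom_sizes
  labels <- lapply(cs, function(L)
    rep("intergenic", L))
  paint <- function(chrom, lo, hi, lab) {
    lo <- max(lo, 1L); hi <- min(hi, cs[[chrom]])
    if (lo <= hi) labels[[chrom]][lo:hi] <<- lab
  }
  # reverse priority painting: intron, exon, tts, promoter
  for (i in seq_len(nrow(genes)))
    paint(genes$chrom[i], genes$start[i], genes$end[i], "intron")
  for (i in seq_len(nrow(genes))) {
    ex <- models$exons[[genes$gene_id[i]]]
    for (k in seq_along(ex))
      paint(genes$chrom[i], start(ex)[k], end(ex)[k], "exon")
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+")
      paint(genes$chrom[i], genes$tes[i] - tts_up,
            genes$tes[i] + tts_dn, "tts")
    else
      paint(genes$chrom[i], genes$tes[i] - tts_dn,
            genes$tes[i] + tts_up, "tts")
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+")
      paint(genes$chrom[i], genes$tss[i] - prom_up,
            genes$tss[i] + prom_dn, "promoter")
    else
      paint(genes$chrom[i], genes$tss[i] - prom_dn,
            genes$tss[i] + prom_up, "promoter")
  }
  mid <- start(gr) + floor(width(gr) / 2)
  vapply(seq_along(gr), function(i)
    labels[[as.character(seqnames(gr))[i]]][mid[i]], "")
}

# random toy genome with genes and models, for oracle-equivalence runs
random_toy_models <- function(len = 10000L, n_genes = 3L,
                              chrom = "chrA") {
  cs <- setNames(len, chrom)
  slots <- seq(1L, len - 1500L, by = max(1500L, len %/% (n_genes + 1L)))
  slots <- head(slots, n_genes)
  gtab <- do.call(rbind, lapply(seq_along(slots), function(i) {
    s <- slots[i] + sample(0:200, 1)
    w <- sample(400:1200, 1)
    e <- min(s + w, len - 10L)
    sp <- sort(sample(s:(e - 50L), 2))
    gene_row(sprintf("tg%02d", i), chrom, sample(c("+", "-"), 1),
             c(sp[1L], sp[2L]), c(sp[1L] + 30L, e))
  }))
  read_gene_models(write_test_gtf(gtab), cs)
}

random_peaks <- function(len, n, min_w = 20L, max_w = 300L,
                         chrom = "chrA") {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sapply(w, function(wi) sample.int(len - wi, 1))
  sort(GRanges(chrom, IRanges(s, width = w)))
}

# small synthetic bundle used by integration-style tests (kept modest
# so the suite stays fast)
small_synthetic_config <- function(seed = 11L, ...) {
  defaults <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 300000L, chr2 = 200000L, chr3 = 100000L),
    n_genes = 60L, n_common_peaks = 60L,
    n_specific_peaks = c(20L, 20L, 20L),
    n_noise_peaks = 15L, n_dpi_up = 8L, n_dpi_down = 8L, n_dpi_mid = 8L,
    n_deg_per_cluster = 5L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
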