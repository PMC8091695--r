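#' Read a chrom.sizes file
#'
#' Two-column TSV (chromosome name, length in bp).  Chromosome lengths
#' anchor coordinate validation, random-region sampling and the
#' normalized-chromosome-length computation.
#'
#' @param path Path to a 2-column TSV.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  validate_chrom_sizes(setNames(as.integer(tab$length), tab$chrom))
}

validate_chrom_sizes <- function(chrom_sizes) {
  if (length(chrom_sizes) == 0L)
    stop("chrom_sizes is empty")
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes)))
    stop("chromosome names must be present and unique")
  if (any(is.na(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("all chromosome lengths must be positive")
  chrom_sizes
}

#' Read gene models from a GTF file
#'
#' Parses gene and exon records, converts to 1-based closed GRanges
#' coordinates, and derives per-gene strand-aware TSS/TES positions and
#' the exonic length (length of the per-gene exon union, not the sum).
#' One TSS per gene record: the gene interval is the union span of its
#' exons (or the explicit gene line when present).
#'
#' @param gtf_path Path to a GTF file (9 columns, attributes containing
#'   `gene_id`).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A `gene_models` object: list with `genes` (data.frame:
#'   gene_id, chrom, start, end, strand, tss, tes, exonic_length),
#'   `exons` (GRangesList keyed by gene_id) and `chrom_sizes`.
#' @export
read_gene_models <- function(gtf_path, chrom_sizes) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0L)
    return(empty_gene_models(chrom_sizes))

  bad <- !(as.character(seqnames(gr)) %in% names(chrom_sizes))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("GTF record %d (gene_id %s) on unknown chromosome '%s'",
                 i, gr$gene_id[i], as.character(seqnames(gr))[i]))
  }
  exons <- gr[gr$type == "exon"]
  gene_lines <- gr[gr$type == "gene"]
  if (length(exons) == 0L) {
    if (length(gene_lines) > 0L)
      stop(sprintf("gene '%s' has no exon features", gene_lines$gene_id[1L]))
    return(empty_gene_models(chrom_sizes))
  }
  orphan <- setdiff(gene_lines$gene_id, exons$gene_id)
  if (length(orphan) > 0L)
    stop(sprintf("gene '%s' has no exon features", orphan[1L]))

  ex_by_gene <- S4Vectors::split(granges(exons), exons$gene_id)
  ex_by_gene <- IRanges::reduce(ex_by_gene)  # per-gene exon union
  ids <- names(ex_by_gene)

  chrom  <- vapply(ex_by_gene, function(g)
    as.character(seqnames(g))[1L], character(1))
  strand_by_gene <- vapply(S4Vectors::split(as.character(strand(exons)),
                                            exons$gene_id),
                           `[`, character(1), 1L)[ids]
  if (any(!strand_by_gene %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  gstart <- vapply(ex_by_gene, function(g) min(start(g)), integer(1))
  gend   <- vapply(ex_by_gene, function(g) max(end(g)), integer(1))
  # explicit gene lines may extend beyond the exon span
  if (length(gene_lines) > 0L) {
    m <- match(ids, gene_lines$gene_id)
    hit <- !is.na(m)
    gstart[hit] <- pmin(gstart[hit], start(gene_lines)[m[hit]])
    gend[hit]   <- pmax(gend[hit], end(gene_lines)[m[hit]])
  }
  over_end <- gend > chrom_sizes[chrom]
  if (any(over_end)) {
    i <- which(over_end)[1L]
    stop(sprintf("gene '%s' extends past the end of chromosome '%s'",
                 ids[i], chrom[i]))
  }
  genes <- data.frame(
    gene_id = ids, chrom = chrom,
    start = gstart, end = gend, strand = strand_by_gene,
    tss = ifelse(strand_by_gene == "+", gstart, gend),
    tes = ifelse(strand_by_gene == "+", gend, gstart),
    exonic_length = vapply(ex_by_gene, function(g)
      sum(width(g)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (anyDuplicated(genes$gene_id))
    stop("gene_ids must be unique")
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = ex_by_gene[genes$gene_id],
                 chrom_sizes = chrom_sizes),
            class = "gene_models")
}

empty_gene_models <- function(chrom_sizes) {
  structure(list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), tss = integer(),
                       tes = integer(), exonic_length = integer(),
                       stringsAsFactors = FALSE),
    exons = GRangesList(),
    chrom_sizes = chrom_sizes), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosomes (%s bp)\n",
              nrow(x$genes), length(x$chrom_sizes),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

as_genome_granges <- function(chrom_sizes) {
  GRanges(names(chrom_sizes),
          IRanges(1L, unname(chrom_sizes)),
          seqlengths = chrom_sizes)
}

#' Strand-aware windows around gene TSSs or TESs
#'
#' `promoter_windows()` returns, per gene, the interval covering
#' positions TSS - upstream ... TSS + downstream inclusive in gene
#' orientation (mirrored on the minus strand), clipped to chromosome
#' bounds.  Defaults follow the promoter-peak definition of -2 kb to
#' +100 bp around the TSS.  `tts_windows()` is the analogue around the
#' transcription end site (default -100 bp to +1 kb).  A window falling
#' entirely off its chromosome is returned with zero width.
#'
#' @param models A `gene_models` object.
#' @param upstream,downstream Window extent in bp (>= 0), in gene
#'   orientation.
#' @param genes Optional character vector of gene_ids to restrict to.
#' @return GRanges, one range per gene, named by gene_id.
#' @export
promoter_windows <- function(models, upstream = 2000, downstream = 100,
                             genes = NULL) {
  anchor_windows(models, "tss", upstream, downstream, genes)
}

#' @rdname promoter_windows
#' @export
tts_windows <- function(models, upstream = 100, downstream = 1000,
                        genes = NULL) {
  anchor_windows(models, "tes", upstream, downstream, genes)
}

anchor_windows <- function(models, anchor, upstream, downstream, genes) {
  stopifnot(upstream >= 0, downstream >= 0)
  g <- models$genes
  if (!is.null(genes)) {
    miss <- setdiff(genes, g$gene_id)
    if (length(miss)) stop("unknown gene_id: ", miss[1L])
    g <- g[match(genes, g$gene_id), , drop = FALSE]
  }
  if (nrow(g) == 0L)
    return(GRanges(seqlengths = models$chrom_sizes))
  pos <- g[[anchor]]
  plus <- g$strand == "+"
  lo <- ifelse(plus, pos - upstream, pos - downstream)
  hi <- ifelse(plus, pos + downstream, pos + upstream)
  clen <- unname(models$chrom_sizes[g$chrom])
  # clip; an entirely off-chromosome window degenerates to zero width
  lo2 <- pmax(lo, 1L); hi2 <- pmin(hi, clen)
  empty <- hi < 1L | lo > clen
  lo2[empty] <- pmin(pmax(lo[empty], 1L), clen[empty])
  hi2[empty] <- lo2[empty] - 1L
  gr <- GRanges(g$chrom, IRanges(lo2, hi2), strand = g$strand,
                seqlengths = models$chrom_sizes[
                  unique(c(g$chrom, names(models$chrom_sizes)))])
  names(gr) <- g$gene_id
  gr$gene_id <- g$gene_id
  gr
}

#' Annotation window configuration
#'
#' Collects the window extents and the feature-class priority used by
#' [classify_intervals()] and [annotate_peaks()], so the classification
#' scheme is explicit and auditable.  Defaults: promoter -2000/+100,
#' proximal promoter -1000/+100, TTS window -100/+1000; priority
#' promoter > tts > exon > intron > intergenic.
#'
#' @param promoter_upstream,promoter_downstream Promoter window bp.
#' @param proximal_upstream,proximal_downstream Proximal-promoter bp.
#' @param tts_upstream,tts_downstream TTS window bp.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(promoter_upstream = 2000,
                              promoter_downstream = 100,
                              proximal_upstream = 1000,
                              proximal_downstream = 100,
                              tts_upstream = 100,
                              tts_downstream = 1000) {
  structure(list(promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 proximal_upstream = proximal_upstream,
                 proximal_downstream = proximal_downstream,
                 tts_upstream = tts_upstream,
                 tts_downstream = tts_downstream,
                 priority = c("promoter", "tts", "exon", "intron",
                              "intergenic")),
            class = "annotation_config")
}

#' Interval midpoints
#'
#' Midpoint of an interval of length L starting at 1-based position s is
#' s + floor(L/2); for even lengths this is the left-of-center position.
#'
#' @param gr GRanges.
#' @return GRanges of width-1 midpoint positions (metadata preserved).
#' @export
interval_midpoints <- function(gr) {
  pos <- start(gr) + floor(width(gr) / 2)
  out <- GRanges(seqnames(gr), IRanges(pos, width = 1L))
  seqlengths(out) <- seqlengths(gr)[seqlevels(out)]
  mcols(out) <- mcols(gr)
  out
}

#' Classify intervals into genomic feature classes
#'
#' Classifies each interval by the feature overlapping its midpoint,
#' with priority promoter > tts > exon > intron > intergenic (so the
#' classes are mutually exclusive).  The proximal-promoter flag is set
#' when the midpoint additionally falls in the narrower proximal window
#' around a TSS; it is meaningful only for intervals classified
#' promoter.
#'
#' @param gr GRanges of intervals (e.g. peaks).
#' @param models A `gene_models` object.
#' @param config An [annotation_config()].
#' @return data.frame with columns `class` (factor with the five class
#'   levels) and `proximal` (logical).
#' @export
classify_intervals <- function(gr, models,
                               config = annotation_config()) {
  bad <- !(as.character(seqnames(gr)) %in% names(models$chrom_sizes))
  if (any(bad))
    stop("interval on unknown chromosome: ",
         as.character(seqnames(gr))[which(bad)[1L]])
  mid <- interval_midpoints(gr)
  n <- length(gr)
  cls <- factor(rep("intergenic", n), levels = config$priority)
  if (nrow(models$genes) > 0L && n > 0L) {
    hit <- function(win) overlapsAny(mid, win, ignore.strand = TRUE)
    gene_bodies <- GRanges(models$genes$chrom,
                           IRanges(models$genes$start, models$genes$end))
    in_exon <- hit(unlist(models$exons, use.names = FALSE))
    in_body <- hit(gene_bodies)
    in_tts  <- hit(tts_windows(models, config$tts_upstream,
                               config$tts_downstream))
    in_prom <- hit(promoter_windows(models, config$promoter_upstream,
                                    config$promoter_downstream))
    cls[in_body]  <- "intron"
    cls[in_exon]  <- "exon"
    cls[in_tts]   <- "tts"
    cls[in_prom]  <- "promoter"
  }
  prox <- if (nrow(models$genes) > 0L && n > 0L) {
    overlapsAny(mid, promoter_windows(models, config$proximal_upstream,
                                      config$proximal_downstream),
                ignore.strand = TRUE) & cls == "promoter"
  } else rep(FALSE, n)
  data.frame(class = cls, proximal = prox)
}

# nearest TSS per midpoint with deterministic tie-breaking:
# minimal |midpoint - TSS|, ties to the lexicographically smaller gene_id
nearest_tss <- function(mid_pos, mid_chrom, genes) {
  n <- length(mid_pos)
  out_gene <- rep(NA_character_, n)
  out_dist <- rep(NA_integer_, n)
  for (ch in unique(mid_chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(mid_chrom == ch)
    if (length(gi) == 0L) next
    g <- genes[gi, , drop = FALSE]
    for (j in pi) {
      d <- abs(mid_pos[j] - g$tss)
      dmin <- min(d)
      cand <- which(d == dmin)
      k <- cand[order(g$gene_id[cand])][1L]
      out_gene[j] <- g$gene_id[k]
      out_dist[j] <- if (g$strand[k] == "+") mid_pos[j] - g$tss[k]
                     else g$tss[k] - mid_pos[j]
    }
  }
  list(gene_id = out_gene, tss_dist = out_dist)
}

#' Annotate peaks with feature class, nearest gene and TSS distance
#'
#' Each peak is classified at its midpoint ([classify_intervals()]) and
#' assigned the gene whose TSS is closest to that midpoint (ties broken
#' by lexicographically smaller gene_id).  The signed distance is in
#' gene orientation: negative = upstream of the TSS.
#'
#' @inheritParams classify_intervals
#' @param peaks GRanges of peaks.
#' @return The input GRanges with added metadata columns `class`,
#'   `proximal`, `gene_id` and `tss_dist`.
#' @export
annotate_peaks <- function(peaks, models, config = annotation_config()) {
  cl <- classify_intervals(peaks, models, config)
  peaks$class <- cl$class
  peaks$proximal <- cl$proximal
  mid <- interval_midpoints(peaks)
  nt <- nearest_tss(start(mid), as.character(seqnames(mid)), models$genes)
  peaks$gene_id <- nt$gene_id
  peaks$tss_dist <- nt$tss_dist
  peaks
}

#' Feature-class composition of an annotated peak set
#'
#' @param annotated GRanges from [annotate_peaks()].
#' @return data.frame with class, count and percentage (summing to 100
#'   over a non-empty set).
#' @export
feature_class_table <- function(annotated) {
  counts <- table(annotated$class)
  data.frame(class = names(counts),
             count = as.integer(counts),
             percent = if (length(annotated)) 100 * as.integer(counts) /
               length(annotated) else rep(0, length(counts)),
             stringsAsFactors = FALSE)
}

#' Write an annotated peak set as BED6+ (class, gene_id, distance)
#'
#' @param annotated GRanges from [annotate_peaks()].
#' @param path Output path.
#' @export
write_annotated_peaks <- function(annotated, path) {
  df <- data.frame(
    chrom = as.character(seqnames(annotated)),
    start = start(annotated) - 1L, end = end(annotated),
    name = if (!is.null(annotated$id)) annotated$id else
      paste0("peak_", seq_along(annotated)),
    score = 0L, strand = ".",
    class = as.character(annotated$class),
    gene_id = annotated$gene_id,
    tss_dist = annotated$tss_dist)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
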