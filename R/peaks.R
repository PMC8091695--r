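#' Read a peak file (BED3, BED6 or narrowPeak)
#'
#' Validating tabular reader for the three peak dialects.  BED
#' half-open 0-based coordinates are converted to the 1-based closed
#' GRanges convention.  Missing optional columns are defaulted (signal
#' 0, p/q scores 0, summit absent); the result is sorted by
#' (chrom, start, end).  Malformed lines are rejected with their line
#' number.
#'
#' @param path Path to the peak file.
#' @param dialect One of "BED3", "BED6", "narrowPeak".
#' @param chrom_sizes Optional named lengths; when given, peaks beyond
#'   chromosome bounds are rejected.
#' @param label Label stored on the returned set (e.g. stage or
#'   replicate name).
#' @return Sorted GRanges with metadata columns id, signal, pscore,
#'   qscore, summit_offset.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "BED3", "BED6"),
                       chrom_sizes = NULL, label = basename(path)) {
  dialect <- match.arg(dialect)
  ncol_needed <- c(narrowPeak = 10L, BED3 = 3L, BED6 = 6L)[[dialect]]
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(empty_peakset(chrom_sizes, label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_needed))
    stop(sprintf("line %d: expected %d columns for %s, found %d",
                 which(nf < ncol_needed)[1L], ncol_needed, dialect,
                 nf[which(nf < ncol_needed)[1L]]))
  mat <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
  chrom <- mat[, 1L]
  start0 <- suppressWarnings(as.integer(mat[, 2L]))
  end0 <- suppressWarnings(as.integer(mat[, 3L]))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop(sprintf("line %d: non-numeric coordinates", which(bad)[1L]))
  if (any(start0 >= end0))
    stop(sprintf("line %d: start >= end", which(start0 >= end0)[1L]))
  if (any(start0 < 0))
    stop(sprintf("line %d: negative start", which(start0 < 0)[1L]))
  n <- length(lines)
  id <- if (ncol_needed >= 6L) mat[, 4L] else
    paste0(label, "_", seq_len(n))
  if (anyDuplicated(id))
    id <- make.unique(id, sep = "_dup")
  signal <- if (dialect == "narrowPeak")
    as.numeric(mat[, 7L]) else if (dialect == "BED6")
      as.numeric(mat[, 5L]) else rep(0, n)
  pscore <- if (dialect == "narrowPeak") as.numeric(mat[, 8L]) else rep(0, n)
  qscore <- if (dialect == "narrowPeak") as.numeric(mat[, 9L]) else rep(0, n)
  summit <- if (dialect == "narrowPeak") as.integer(mat[, 10L]) else
    rep(NA_integer_, n)
  summit[!is.na(summit) & summit < 0] <- NA_integer_
  if (!is.null(chrom_sizes)) {
    unk <- !(chrom %in% names(chrom_sizes))
    if (any(unk))
      stop(sprintf("line %d: unknown chromosome '%s'",
                   which(unk)[1L], chrom[which(unk)[1L]]))
    over <- end0 > chrom_sizes[chrom]
    if (any(over))
      stop(sprintf("line %d: peak extends past chromosome end",
                   which(over)[1L]))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0),
                id = id, signal = signal, pscore = pscore,
                qscore = qscore, summit_offset = summit)
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- names(chrom_sizes)
    seqlengths(gr) <- unname(chrom_sizes)
  }
  gr <- sort(gr, ignore.strand = TRUE)
  mcols(gr)$label <- NULL
  attr(gr, "label") <- label
  gr
}

empty_peakset <- function(chrom_sizes, label) {
  gr <- GRanges(id = character(), signal = numeric(),
                pscore = numeric(), qscore = numeric(),
                summit_offset = integer())
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- names(chrom_sizes)
    seqlengths(gr) <- unname(chrom_sizes)
  }
  attr(gr, "label") <- label
  gr
}

#' Write peaks as BED or narrowPeak
#'
#' @param peaks GRanges (metadata columns used when present).
#' @param path Output path.
#' @param dialect One of "BED3", "BED6", "narrowPeak".
#' @export
write_peaks <- function(peaks, path,
                        dialect = c("narrowPeak", "BED3", "BED6")) {
  dialect <- match.arg(dialect)
  n <- length(peaks)
  id <- if (!is.null(peaks$id)) peaks$id else paste0("peak_", seq_len(n))
  getcol <- function(col) if (!is.null(mcols(peaks)[[col]]))
    mcols(peaks)[[col]] else rep(0, n)
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks))
  if (dialect != "BED3") {
    df$name <- id
    df$score <- as.integer(pmin(1000, round(getcol("signal"))))
    df$strand <- "."
  }
  if (dialect == "narrowPeak") {
    summit <- if (!is.null(peaks$summit_offset)) peaks$summit_offset else
      rep(NA_integer_, n)
    summit[is.na(summit)] <- -1L
    df$signal <- getcol("signal")
    df$pscore <- getcol("pscore")
    df$qscore <- getcol("qscore")
    df$summit <- summit
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Consensus peaks across replicates
#'
#' Maximal intervals of positions covered by at least one peak in EVERY
#' replicate ("shared by all replicates, then merged"): the
#' base-level intersection across replicates, merged into contiguous
#' runs.  The result is non-overlapping and sorted, and every output
#' position is covered in all inputs.
#'
#' @param replicate_sets List of >= 1 GRanges (one per replicate).  With
#'   a single replicate the merged input is returned with a warning.
#' @param min_width Minimum consensus interval width in bp (default 1 =
#'   no filter).
#' @param label Label for the consensus set (stored as attribute and
#'   used to form peak ids).
#' @return Sorted GRanges with metadata column `id`.
#' @export
consensus_peaks <- function(replicate_sets, min_width = 1L,
                            label = "consensus") {
  if (length(replicate_sets) == 0L)
    stop("at least one replicate peak set is required")
  if (length(replicate_sets) == 1L)
    warning("single replicate: consensus is the merged input")
  cons <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE),
    lapply(replicate_sets, function(g)
      reduce(granges(g), ignore.strand = TRUE)))
  cons <- sort(reduce(cons, ignore.strand = TRUE), ignore.strand = TRUE)
  cons <- cons[width(cons) >= min_width]
  if (length(cons))
    cons$id <- sprintf("%s_%05d", label, seq_along(cons))
  else cons$id <- character(0)
  attr(cons, "label") <- label
  cons
}

#' Partition stage consensus sets into stage-specific and common peaks
#'
#' A stage's peak is *specific* iff it overlaps (>= `min_overlap` bp) no
#' peak of any other stage's consensus set.  *Common* peaks are the
#' peaks of the reference stage (by default the first = earliest stage)
#' that are overlapped by every other stage's set, giving a single peak
#' universe for differential peak-intensity analysis.
#'
#' @param stage_sets Named list of >= 2 consensus GRanges, one per
#'   stage, in stage order (first = reference).
#' @param min_overlap Minimum overlap in bp to count as shared
#'   (default 1).
#' @return A `stage_partition` object: list with `specific` (named list
#'   of GRanges), `common` (GRanges in reference-stage coordinates),
#'   `reference` (stage name) and `counts` (data.frame).
#' @export
stage_partition <- function(stage_sets, min_overlap = 1L) {
  if (length(stage_sets) < 2L)
    stop("at least two stage sets are required")
  if (is.null(names(stage_sets)))
    names(stage_sets) <- paste0("stage", seq_along(stage_sets))
  stages <- names(stage_sets)
  specific <- lapply(stages, function(s) {
    others <- stage_sets[setdiff(stages, s)]
    keep <- rep(TRUE, length(stage_sets[[s]]))
    for (o in others)
      keep <- keep & countOverlaps(stage_sets[[s]], o,
                                   minoverlap = min_overlap,
                                   ignore.strand = TRUE) == 0L
    stage_sets[[s]][keep]
  })
  names(specific) <- stages
  ref <- stage_sets[[1L]]
  shared <- rep(TRUE, length(ref))
  for (o in stage_sets[-1L])
    shared <- shared & countOverlaps(ref, o, minoverlap = min_overlap,
                                     ignore.strand = TRUE) > 0L
  common <- ref[shared]
  counts <- data.frame(
    stage = c(stages, "common"),
    n = c(vapply(specific, length, integer(1)), length(common)),
    category = c(rep("specific", length(stages)), "common"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(specific = specific, common = common,
                 reference = stages[1L], counts = counts),
            class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat(sprintf("stage_partition (reference: %s)\n", x$reference))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Fraction of the genome covered by a peak set
#'
#' Merged peak bp divided by total genome bp; overlapping peaks are
#' union-counted.
#'
#' @param peaks GRanges.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return Fraction in [0, 1].
#' @export
genome_coverage <- function(peaks, chrom_sizes) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  total <- sum(as.numeric(chrom_sizes))
  if (length(peaks) == 0L) return(0)
  if (any(!as.character(seqnames(peaks)) %in% names(chrom_sizes)))
    stop("peak on chromosome absent from chrom_sizes")
  covered <- sum(as.numeric(width(reduce(granges(peaks),
                                         ignore.strand = TRUE))))
  covered / total
}

#' Per-chromosome peak counts
#'
#' @param peaks GRanges.
#' @param chrom_sizes Optional named lengths; when given, chromosomes
#'   with zero peaks are included with count 0.
#' @return Named integer vector of counts.
#' @export
chrom_peak_counts <- function(peaks, chrom_sizes = NULL) {
  lev <- if (!is.null(chrom_sizes)) names(chrom_sizes) else
    sort(unique(as.character(seqnames(peaks))))
  counts <- table(factor(as.character(seqnames(peaks)), levels = lev))
  setNames(as.integer(counts), lev)
}
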