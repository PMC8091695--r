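#' Read position-weight matrices from a minimal MEME-format file
#'
#' Parses MOTIF blocks with their letter-probability matrices and the
#' background letter frequencies (uniform when the file states none).
#'
#' @param path Path to a MEME-format motif file (alphabet ACGT).
#' @return List of `pwm` objects: list(motif_id, matrix (width x 4,
#'   columns A,C,G,T), background (length-4)).
#' @export
read_meme_pwms <- function(path) {
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1L] + 1L], "\\s+")[[1L]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF", lines)
  pwms <- lapply(seq_along(starts), function(i) {
    id <- strsplit(lines[starts[i]], "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > starts[i]][1L]
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])
    w <- as.integer(w)
    mat <- do.call(rbind, lapply(lines[(hdr + 1L):(hdr + w)], function(l)
      as.numeric(strsplit(l, "\\s+")[[1L]])))
    colnames(mat) <- c("A", "C", "G", "T")
    validate_pwm(list(motif_id = id, matrix = mat, background = bg))
  })
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  pwms
}

validate_pwm <- function(pwm) {
  if (nrow(pwm$matrix) < 4L) stop("PWM width must be >= 4")
  if (any(abs(rowSums(pwm$matrix) - 1) > 1e-6))
    stop("PWM rows must sum to 1")
  structure(pwm, class = "pwm")
}

#' Build a PWM object from a probability matrix
#'
#' @param motif_id Identifier.
#' @param matrix Width x 4 base-probability matrix (columns A,C,G,T).
#' @param background Length-4 background probabilities.
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, matrix,
                background = c(A = 0.25, C = 0.25, G = 0.25,
                               T = 0.25)) {
  colnames(matrix) <- c("A", "C", "G", "T")
  validate_pwm(list(motif_id = motif_id, matrix = matrix,
                    background = background))
}

# log-odds score matrix with pseudocount on the probabilities
pwm_logodds <- function(pwm, pseudocount = 1e-3) {
  pr <- pwm$matrix + pseudocount
  pr <- pr / rowSums(pr)
  bg <- pwm$background + pseudocount
  bg <- bg / sum(bg)
  log2(sweep(pr, 2L, bg, "/"))
}

#' Maximum achievable log-odds score of a PWM
#'
#' @param pwm A `pwm` object.
#' @param pseudocount Probability pseudocount (default 1e-3).
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(pwm, pseudocount = 1e-3) {
  sum(apply(pwm_logodds(pwm, pseudocount), 1L, max))
}

#' Peak-centered fixed-width windows
#'
#' The window midpoint +/- halfwidth around each peak center (a 200-bp
#' window at the default halfwidth 100), clipped to chromosome bounds.
#'
#' @param peaks GRanges of peaks (seqlengths used for clipping when
#'   set).
#' @param halfwidth Half-window size in bp (default 100).
#' @return GRanges of windows, metadata preserved.
#' @export
centered_windows <- function(peaks, halfwidth = 100) {
  stopifnot(halfwidth >= 1)
  mid <- interval_midpoints(peaks)
  sl <- seqlengths(peaks)[as.character(seqnames(mid))]
  s <- pmax(start(mid) - halfwidth, 1L)
  e <- start(mid) + halfwidth - 1L
  bounded <- !is.na(sl)
  e[bounded] <- pmin(e[bounded], sl[bounded])
  win <- GRanges(seqnames(mid), IRanges(s, e))
  seqinfo(win) <- seqinfo(peaks)
  mcols(win) <- mcols(peaks)
  win
}

#' Extract window sequences from a FASTA file
#'
#' @param intervals GRanges.
#' @param fasta Path to a FASTA file or a Biostrings::DNAStringSet.
#' @return Uppercase character vector of sequences, same order as
#'   `intervals` (named by the `id` column when present).
#' @export
extract_sequences <- function(intervals, fasta) {
  seqs <- if (is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(intervals) == 0L) return(character(0))
  chrom <- as.character(seqnames(intervals))
  if (any(!chrom %in% names(seqs)))
    stop("chromosome absent from FASTA: ",
         chrom[which(!chrom %in% names(seqs))[1L]])
  if (any(end(intervals) > width(seqs)[match(chrom, names(seqs))]))
    stop("interval extends beyond sequence length")
  out <- toupper(as.character(Biostrings::subseq(
    seqs[chrom], start = start(intervals), end = end(intervals))))
  names(out) <- if (!is.null(intervals$id)) intervals$id else NULL
  out
}

#' Scan a sequence with a PWM on both strands
#'
#' Reports every window start position (1-based, forward-strand
#' coordinates) where the log-odds score reaches the threshold on the
#' forward or the reverse-complement strand.  Windows containing N are
#' skipped.
#'
#' @param sequence Character scalar over A,C,G,T,N.
#' @param pwm A `pwm` object.
#' @param threshold Log-odds threshold; default 80 percent of the
#'   motif's maximum score.
#' @param pseudocount Probability pseudocount (default 1e-3).
#' @return data.frame: position, strand, score.
#' @export
pwm_scan <- function(sequence, pwm, threshold = NULL,
                     pseudocount = 1e-3) {
  lo <- pwm_logodds(pwm, pseudocount)
  if (is.null(threshold))
    threshold <- 0.8 * pwm_max_score(pwm, pseudocount)
  w <- nrow(lo)
  s <- toupper(sequence)
  n <- nchar(s)
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric())
  if (n < w) return(empty)
  base_idx <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  npos <- n - w + 1L
  # per-position column scores; windows touching an N become NA
  fwd <- numeric(npos); rev_ <- numeric(npos)
  for (k in seq_len(w)) {
    b <- base_idx[k:(k + npos - 1L)]
    fwd <- fwd + lo[k, ][b]
    rev_ <- rev_ + lo[w - k + 1L, c(4L, 3L, 2L, 1L)][b]  # revcomp strand
  }
  hits_f <- which(!is.na(fwd) & fwd >= threshold)
  hits_r <- which(!is.na(rev_) & rev_ >= threshold)
  out <- rbind(
    data.frame(position = hits_f, strand = rep("+", length(hits_f)),
               score = fwd[hits_f]),
    data.frame(position = hits_r, strand = rep("-", length(hits_r)),
               score = rev_[hits_r]))
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Motif enrichment of target vs background sequence sets
#'
#' Counts, per motif, the sequences with at least one PWM hit in the
#' target and background sets and computes the upper-tail
#' hypergeometric p-value on the pooled 2x2 table (drawing the target
#' set from the pooled sequences).
#'
#' @param target_seqs,background_seqs Character vectors of sequences.
#' @param pwms List of `pwm` objects.
#' @param alpha Significance cutoff for the enrichment flag
#'   (default 0.01).
#' @param threshold,pseudocount Passed to [pwm_scan()].
#' @return data.frame: motif_id, target_with_hit, target_total,
#'   background_with_hit, background_total, p, enriched.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             alpha = 0.01, threshold = NULL,
                             pseudocount = 1e-3) {
  if (length(target_seqs) == 0L || length(background_seqs) == 0L)
    stop("target and background sets must be non-empty")
  if (length(pwms) == 0L)
    return(data.frame(motif_id = character(), target_with_hit = integer(),
                      target_total = integer(),
                      background_with_hit = integer(),
                      background_total = integer(), p = numeric(),
                      enriched = logical()))
  rows <- lapply(pwms, function(pw) {
    has_hit <- function(seqs) vapply(seqs, function(s)
      nrow(pwm_scan(s, pw, threshold, pseudocount)) > 0L, logical(1))
    th <- sum(has_hit(target_seqs)); bh <- sum(has_hit(background_seqs))
    tt <- length(target_seqs); bt <- length(background_seqs)
    p <- phyper(th - 1L, th + bh, tt + bt - th - bh, tt,
                lower.tail = FALSE)
    data.frame(motif_id = pw$motif_id, target_with_hit = th,
               target_total = tt, background_with_hit = bh,
               background_total = bt, p = p, enriched = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Reverse complement of a DNA string
#'
#' @param sequence Character scalar over A,C,G,T,N.
#' @return Character scalar.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
}
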