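#' Read a count matrix and its sample sheet
#'
#' The count TSV has a `feature_id` column followed by one integer
#' column per sample; the sample sheet TSV has columns sample_id,
#' stage, replicate.  Sample order in the sheet must match the count
#' columns (they are aligned by sample_id).
#'
#' @param counts_path,samples_path Paths to the two TSVs.
#' @return List with `counts` (integer matrix, features x samples) and
#'   `samples` (data.frame).
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- read.table(counts_path, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab[[1L]]
  storage.mode(counts) <- "integer"
  samples <- read.table(samples_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  validate_count_matrix(counts, samples)
  counts <- counts[, samples$sample_id, drop = FALSE]
  list(counts = counts, samples = samples)
}

validate_count_matrix <- function(counts, samples) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  if (any(is.na(counts))) stop("missing counts")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_ids")
  if (!all(samples$sample_id %in% colnames(counts)))
    stop("sample sheet names a sample absent from the count matrix")
  invisible(TRUE)
}

#' FPKM expression values
#'
#' fpkm = count * 1e9 / (feature length * library size), per cell.
#' Library sizes default to per-sample column sums.
#'
#' @param counts Integer matrix, features x samples.
#' @param lengths Named numeric vector of feature lengths in bp (for
#'   genes, the exonic-union length); must cover all rows of `counts`.
#' @param library_sizes Optional named/per-column library sizes.
#' @return Numeric matrix of FPKM values, same dimensions as `counts`.
#' @export
fpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  lens <- lengths[rownames(counts)]
  if (any(is.na(lens)))
    stop("missing length for feature: ",
         rownames(counts)[which(is.na(lens))[1L]])
  if (any(lens <= 0)) stop("feature lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(sweep(counts * 1e9, 1L, lens, "/"), 2L, library_sizes, "/")
}

#' Expression filter: detectably expressed genes
#'
#' A gene is kept iff some stage has at least `min_samples` samples
#' with FPKM strictly greater than `min_fpkm`.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param samples Sample sheet data.frame (sample_id, stage).
#' @param min_fpkm Strict lower threshold (default 1).
#' @param min_samples Samples required above threshold within one stage
#'   (default 3).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, samples, min_fpkm = 1,
                             min_samples = 3) {
  stages <- unique(samples$stage)
  keep <- rep(FALSE, nrow(expr))
  for (s in stages) {
    cols <- samples$sample_id[samples$stage == s]
    keep <- keep |
      rowSums(expr[, cols, drop = FALSE] > min_fpkm) >= min_samples
  }
  rownames(expr)[keep]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across features of the
#' ratio of each sample's count to the feature's geometric mean,
#' computed over features with nonzero counts in all samples, then
#' rescaled so the factors' geometric mean is 1.  When no feature is
#' nonzero everywhere, falls back to library-size ratios with a
#' warning.
#'
#' @param counts Integer matrix, features x samples.
#' @param warn Emit the fallback warning (internal callers silence it).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts, warn = TRUE) {
  if (ncol(counts) == 1L)
    return(setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    if (warn)
      warning("no feature nonzero in all samples; ",
              "falling back to library-size ratios")
    sf <- colSums(counts)
  } else {
    lg <- log(counts[allpos, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- exp(apply(lg - geo, 2L, stats::median))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Negative-binomial Wald differential test
#'
#' Shared engine for differential peak intensity (ATAC read counts in
#' peaks) and differential gene expression.  Counts are normalized by
#' median-of-ratios size factors; per-feature dispersion is a pooled
#' method-of-moments estimate (floored at 1e-8); the log2 fold change
#' is computed from normalized group means with pseudo-count 0.5; the
#' Wald statistic is referred to a t distribution with nA + nB - 2
#' degrees of freedom (small-sample calibration); p-values are
#' Benjamini-Hochberg adjusted over the tested features.  Features with
#' all-zero counts are excluded from testing and from the BH
#' denominator.
#'
#' @param counts Integer matrix, features x samples.
#' @param samples Sample sheet data.frame (sample_id, stage).
#' @param contrast Character pair c(stage_B, stage_A): positive log2FC
#'   means higher in stage_B.
#' @param alpha Adjusted-p threshold for the direction call
#'   (default 0.05).
#' @param lfc_min Minimum |log2FC| for the direction call (default 1).
#' @param sf Optional precomputed size factors (named, covering all
#'   used samples).
#' @return data.frame of per-feature records: feature_id, base_mean,
#'   log2fc, p, padj, direction (up/down/ns).
#' @export
nb_differential <- function(counts, samples, contrast,
                            alpha = 0.05, lfc_min = 1, sf = NULL) {
  stopifnot(length(contrast) == 2L)
  for (s in contrast)
    if (!s %in% samples$stage) stop("stage absent from sample sheet: ", s)
  colsB <- samples$sample_id[samples$stage == contrast[1L]]
  colsA <- samples$sample_id[samples$stage == contrast[2L]]
  if (length(colsA) < 2L || length(colsB) < 2L)
    stop("both stages need >= 2 replicates")
  sub <- counts[, c(colsA, colsB), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(sub, warn = FALSE)
  q <- sweep(sub, 2L, sf[colnames(sub)], "/")
  tested <- rowSums(sub) > 0
  qA <- q[, colsA, drop = FALSE]; qB <- q[, colsB, drop = FALSE]
  nA <- length(colsA); nB <- length(colsB)
  muA <- rowMeans(qA); muB <- rowMeans(qB)
  vA <- apply(qA, 1L, var); vB <- apply(qB, 1L, var)
  mu_pool <- (nA * muA + nB * muB) / (nA + nB)
  v_pool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  disp <- pmax((v_pool - mu_pool) / pmax(mu_pool, 1e-8)^2, 1e-8)
  lfc <- log2((muB + 0.5) / (muA + 0.5))
  # delta-method variance of log group means under NB(mu, disp)
  vlA <- (muA + disp * muA^2) / nA / pmax(muA, 0.5)^2
  vlB <- (muB + disp * muB^2) / nB / pmax(muB, 0.5)^2
  z <- (log(muB + 0.5) - log(muA + 0.5)) / sqrt(vlA + vlB)
  p <- 2 * pt(-abs(z), df = nA + nB - 2)
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  direction <- rep("ns", length(p))
  direction[!is.na(padj) & padj < alpha & lfc > lfc_min] <- "up"
  direction[!is.na(padj) & padj < alpha & lfc < -lfc_min] <- "down"
  data.frame(feature_id = rownames(counts),
             base_mean = mu_pool, log2fc = lfc, p = p, padj = padj,
             direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count significant down/up calls
#'
#' Applies the significance thresholds (adjusted p < alpha and
#' |log2FC| > lfc_min) to a differential result table and counts the
#' down- and up-regulated features and their total.
#'
#' @param records data.frame from [nb_differential()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_min Minimum |log2FC| (default 1).
#' @return Named integer vector c(down, up, total).
#' @export
significance_summary <- function(records, alpha = 0.05, lfc_min = 1) {
  ok <- !is.na(records$padj) & records$padj < alpha
  down <- sum(ok & records$log2fc < -lfc_min)
  up <- sum(ok & records$log2fc > lfc_min)
  c(down = down, up = up, total = down + up)
}

#' Write a differential result table as TSV
#'
#' @param records data.frame from [nb_differential()].
#' @param path Output path.
#' @export
write_differential <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
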