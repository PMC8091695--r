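#' Map genes to their proximal-promoter ACRs
#'
#' Collects, per gene, the annotated peaks whose midpoint lies in that
#' gene's proximal promoter window (peaks classified promoter with the
#' proximal flag, keyed by their nearest gene).  Also reports how many
#' genes carry one vs more than one proximal-promoter ACR.
#'
#' @param annotated GRanges from [annotate_peaks()].
#' @return A `promoter_acr_map`: list with `map` (data.frame gene_id,
#'   acr_id, length) and `count_distribution` (data.frame gene_id,
#'   n_acrs).
#' @export
map_promoter_acrs <- function(annotated) {
  sel <- annotated$class == "promoter" & annotated$proximal &
    !is.na(annotated$gene_id)
  hits <- annotated[sel]
  map <- data.frame(gene_id = hits$gene_id,
                    acr_id = hits$id,
                    length = width(hits),
                    stringsAsFactors = FALSE, row.names = NULL)
  map <- map[order(map$gene_id, map$acr_id), , drop = FALSE]
  rownames(map) <- NULL
  counts <- table(map$gene_id)
  structure(list(
    map = map,
    count_distribution = data.frame(gene_id = names(counts),
                                    n_acrs = as.integer(counts),
                                    stringsAsFactors = FALSE,
                                    row.names = NULL)),
    class = "promoter_acr_map")
}

#' Per-gene ACR length statistic
#'
#' For single-ACR genes, `single` is the length of that ACR; multi-ACR
#' genes are summarized by `max` or `total` length.
#'
#' @param acr_map A `promoter_acr_map`.
#' @param statistic One of "single", "max", "total".
#' @return Named numeric vector, gene_id -> length statistic.  With
#'   `single`, only genes with exactly one ACR are returned; with `max`
#'   or `total`, only genes with more than one.
#' @export
acr_length_statistic <- function(acr_map,
                                 statistic = c("single", "max",
                                               "total")) {
  statistic <- match.arg(statistic)
  m <- acr_map$map
  n <- table(m$gene_id)
  if (statistic == "single") {
    keep <- m$gene_id %in% names(n)[n == 1L]
    return(setNames(as.numeric(m$length[keep]), m$gene_id[keep]))
  }
  keep <- m$gene_id %in% names(n)[n > 1L]
  m <- m[keep, , drop = FALSE]
  f <- if (statistic == "max") max else sum
  vapply(split(m$length, m$gene_id), f, numeric(1))
}

#' Three equal length groups with the similar-length tie rule
#'
#' Genes are sorted by their ACR-length statistic and cut into three
#' equal groups (top = longest, middle, bottom = shortest).  A run of
#' equal lengths straddling a cut cannot be split "easily": the whole
#' run is assigned to the group that initially holds the greater number
#' of the run's members; an exact 50/50 run goes to the shorter-length
#' side.  The resulting partition is total and deterministic, and
#' depends only on the ranks and tie structure of the lengths.
#'
#' @param gene_lengths Named numeric vector, gene_id -> length
#'   statistic (>= 3 genes).
#' @param statistic Label recorded on the result ("single", "max" or
#'   "total").
#' @return data.frame: gene_id, length, group (factor
#'   top/middle/bottom), statistic.
#' @export
assign_length_groups <- function(gene_lengths,
                                 statistic = c("single", "max",
                                               "total")) {
  statistic <- match.arg(statistic)
  n <- length(gene_lengths)
  if (n < 3L) stop("at least 3 genes are required")
  ord <- order(-gene_lengths, names(gene_lengths))  # descending, top first
  vals <- unname(gene_lengths[ord])
  # initial cuts: last index of top and of middle
  cuts <- c(round(n / 3), round(2 * n / 3))
  for (k in 1:2) {
    cpos <- cuts[k]
    if (cpos <= 0L || cpos >= n) next
    if (vals[cpos] == vals[cpos + 1L]) {
      run <- which(vals == vals[cpos])
      upper <- sum(run <= cpos)   # members initially above the cut
      lower <- sum(run > cpos)
      if (upper > lower) cuts[k] <- max(run)
      else cuts[k] <- min(run) - 1L   # 50/50 -> shorter-length side
    }
  }
  cuts <- sort(pmin(pmax(cuts, 0L), n))
  grp <- rep("bottom", n)
  if (cuts[1L] > 0L) grp[seq_len(cuts[1L])] <- "top"
  if (cuts[2L] > cuts[1L]) grp[(cuts[1L] + 1L):cuts[2L]] <- "middle"
  data.frame(gene_id = names(gene_lengths)[ord],
             length = vals,
             group = factor(grp, levels = c("top", "middle", "bottom")),
             statistic = statistic,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bin mean expression into the five FPKM classes
#'
#' Left-closed/right-open bins [0,2), [2,5), [5,10), [10,30), [30,Inf),
#' labelled B1..B5.
#'
#' @param mean_fpkm Numeric vector of per-gene mean FPKM (>= 0).
#' @return Factor of bin labels, same length/names as input.
#' @export
bin_expression <- function(mean_fpkm) {
  if (any(mean_fpkm < 0)) stop("FPKM values must be non-negative")
  cut(mean_fpkm, breaks = c(0, 2, 5, 10, 30, Inf),
      labels = paste0("B", 1:5), right = FALSE, include.lowest = TRUE)
}

#' Group-by-expression-bin percentage table
#'
#' Rows are length groups, columns the five FPKM bins; each row sums
#' to 100 (an empty group yields a zero row with a warning).
#'
#' @param groups Named factor/character, gene_id -> length group.
#' @param bins Named factor, gene_id -> expression bin (same genes).
#' @return Numeric matrix, groups x 5 bins, of row percentages.
#' @export
group_bin_table <- function(groups, bins) {
  common <- intersect(names(groups), names(bins))
  g <- factor(as.character(groups[common]),
              levels = if (is.factor(groups)) levels(groups)
                       else sort(unique(as.character(groups))))
  b <- factor(as.character(bins[common]), levels = paste0("B", 1:5))
  tab <- table(g, b)
  rs <- rowSums(tab)
  if (any(rs == 0)) warning("empty group(s): ",
                            paste(rownames(tab)[rs == 0], collapse = ", "))
  out <- 100 * sweep(unclass(tab), 1L, pmax(rs, 1L), "/")
  dimnames(out) <- dimnames(tab)
  out
}

#' Per-gene peak-intensity vs expression correlation
#'
#' For each (gene, peak) pair, the Pearson correlation across samples
#' between the peak's normalized read counts and the gene's FPKM.
#' Genes with zero variance on either side get NA and are flagged.
#'
#' @param peak_counts_norm Normalized peak-count matrix,
#'   peaks x samples.
#' @param expr FPKM matrix, genes x samples (same sample columns).
#' @param gene_peak_map data.frame with columns gene_id, peak_id.
#' @return data.frame: gene_id, peak_id, r, flagged (zero-variance).
#' @export
intensity_expression_correlation <- function(peak_counts_norm, expr,
                                             gene_peak_map) {
  cols <- intersect(colnames(peak_counts_norm), colnames(expr))
  if (length(cols) < 3L)
    stop("need >= 3 shared samples to correlate")
  r <- vapply(seq_len(nrow(gene_peak_map)), function(i) {
    g <- gene_peak_map$gene_id[i]; p <- gene_peak_map$peak_id[i]
    x <- peak_counts_norm[p, cols]; y <- expr[g, cols]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  data.frame(gene_id = gene_peak_map$gene_id,
             peak_id = gene_peak_map$peak_id,
             r = r, flagged = is.na(r),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster differentially expressed genes by temporal profile
#'
#' Each gene's FPKM row is z-scored across samples, averaged within
#' stage (giving a stage-profile vector), and the profiles are
#' k-means-clustered (default k = 6, 10 restarts).  Cluster labels are
#' renumbered by descending cluster size (ties by center order) so the
#' labelling is deterministic given the RNG seed.
#'
#' @param expr FPKM matrix of the DEGs, genes x samples.
#' @param samples Sample sheet data.frame (sample_id, stage).
#' @param k Number of clusters (default 6, >= 2).
#' @return List with `clusters` (named integer vector, gene ->
#'   cluster), `centers` (k x stages matrix) and `profiles` (genes x
#'   stages matrix of stage-averaged z-scores).
#' @export
cluster_degs <- function(expr, samples, k = 6) {
  if (k < 2L) stop("k must be >= 2")
  if (nrow(expr) < k) stop("fewer genes than clusters")
  z <- t(scale(t(expr)))
  z[is.na(z)] <- 0  # flat genes carry no profile
  stages <- unique(samples$stage)
  prof <- vapply(stages, function(s)
    rowMeans(z[, samples$sample_id[samples$stage == s], drop = FALSE]),
    numeric(nrow(expr)))
  colnames(prof) <- stages
  km <- kmeans(prof, centers = k, nstart = 10, iter.max = 100)
  size_order <- order(-km$size, km$centers[, 1L])
  relabel <- integer(k); relabel[size_order] <- seq_len(k)
  clusters <- setNames(relabel[km$cluster], rownames(expr))
  centers <- km$centers[size_order, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(clusters = clusters, centers = centers, profiles = prof)
}

#' Hypergeometric overlap significance of two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the
#' seen overlap between two sets drawn from a common universe.
#'
#' @param set_a,set_b Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @return data.frame: set_a_size, set_b_size, universe_size, overlap,
#'   p.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be contained in the universe")
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1L, length(set_a),
              length(universe) - length(set_a), length(set_b),
              lower.tail = FALSE)
  data.frame(set_a_size = length(set_a), set_b_size = length(set_b),
             universe_size = length(universe), overlap = ov, p = p)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same
#' items; 1 = identical up to relabeling, ~0 = random agreement.
#'
#' @param a,b Vectors of cluster labels for the same items.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
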