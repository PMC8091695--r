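#' Sample length-matched random genomic regions
#'
#' One random region per requested length: the chromosome is drawn with
#' probability proportional to its length among chromosomes long enough
#' to hold the region (genome-uniform placement; a `uniform` weighting
#' over chromosomes is available), and the start is uniform on the
#' valid range.  Regions may overlap one another and real peaks — no
#' exclusion is applied.
#'
#' @param lengths Integer vector of region lengths (bp).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param chrom_weighting "length" (default) or "uniform".
#' @return GRanges of sampled regions, same order as `lengths`.
#' @export
sample_random_regions <- function(lengths, chrom_sizes,
                                  chrom_weighting = c("length",
                                                      "uniform")) {
  chrom_weighting <- match.arg(chrom_weighting)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  n <- length(lengths)
  if (n == 0L)
    return(GRanges(seqlengths = chrom_sizes))
  if (any(lengths > max(chrom_sizes)))
    stop("requested length exceeds every chromosome")
  if (any(lengths < 1L))
    stop("region lengths must be >= 1")
  chrom <- character(n)
  # draw per distinct length so eligibility (len <= chrom size) holds
  for (len in unique(lengths)) {
    idx <- which(lengths == len)
    ok <- chrom_sizes >= len
    w <- if (chrom_weighting == "length")
      as.numeric(chrom_sizes[ok]) else rep(1, sum(ok))
    chrom[idx] <- sample(names(chrom_sizes)[ok], length(idx),
                         replace = TRUE, prob = w)
  }
  max_start <- chrom_sizes[chrom] - lengths + 1L  # 1-based start range
  start <- 1L + floor(runif(n) * max_start)
  GRanges(chrom, IRanges(as.integer(start), width = lengths),
          seqlengths = chrom_sizes)
}

#' Permutation fold enrichment of peaks across feature classes
#'
#' Observed per-class peak counts (midpoint classification) are
#' compared with the mean class counts over `n_perm` random region sets
#' matched to the peak lengths.  Fold = observed / expected; classes
#' with expected 0 get fold NaN.  The permutation SD of each class
#' count is reported so tolerance checks can be principled.
#'
#' @param peaks GRanges of peaks.
#' @param models A `gene_models` object.
#' @param chrom_sizes Named chromosome lengths.
#' @param n_perm Number of permutations (default 5000).
#' @param config An [annotation_config()].
#' @param chrom_weighting Passed to [sample_random_regions()].
#' @return data.frame: class, observed, expected, fold, sd, n_perm.
#' @export
fold_enrichment <- function(peaks, models, chrom_sizes,
                            n_perm = 5000,
                            config = annotation_config(),
                            chrom_weighting = "length") {
  stopifnot(n_perm >= 1)
  classes <- config$priority
  obs <- table(factor(
    classify_intervals(peaks, models, config)$class, levels = classes))
  lens <- width(peaks)
  perm_counts <- matrix(0, nrow = n_perm, ncol = length(classes),
                        dimnames = list(NULL, classes))
  for (i in seq_len(n_perm)) {
    rnd <- sample_random_regions(lens, chrom_sizes, chrom_weighting)
    perm_counts[i, ] <- table(factor(
      classify_intervals(rnd, models, config)$class, levels = classes))
  }
  expected <- colMeans(perm_counts)
  sds <- apply(perm_counts, 2L, sd)
  data.frame(class = classes,
             observed = as.integer(obs),
             expected = as.numeric(expected),
             fold = as.integer(obs) / as.numeric(expected),
             sd = if (n_perm > 1) sds else rep(NA_real_, length(classes)),
             n_perm = n_perm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalized chromosome lengths
#'
#' normalized length_i = total peak number * length_i / total genome
#' length, so the values sum to the total peak count and give the peak
#' count each chromosome would carry if peaks were spread uniformly.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param total_peaks Total number of peaks (>= 0).
#' @return Named numeric vector in peak-count units.
#' @export
normalized_chrom_lengths <- function(chrom_sizes, total_peaks) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  stopifnot(total_peaks >= 0)
  setNames(total_peaks * as.numeric(chrom_sizes) /
             sum(as.numeric(chrom_sizes)), names(chrom_sizes))
}

#' Correlation between normalized chromosome length and peak count
#'
#' Pearson correlation over chromosomes between the normalized lengths
#' and the observed per-chromosome peak counts.
#'
#' @param normalized_lengths Named numeric vector
#'   ([normalized_chrom_lengths()]).
#' @param peak_counts Named integer vector ([chrom_peak_counts()]); must
#'   cover the same chromosomes.
#' @return List with `r` and `r_squared`.
#' @export
chrom_correlation <- function(normalized_lengths, peak_counts) {
  if (length(normalized_lengths) < 3L)
    stop("at least 3 chromosomes are required")
  peak_counts <- peak_counts[names(normalized_lengths)]
  if (any(is.na(peak_counts)))
    stop("peak_counts must cover all chromosomes in normalized_lengths")
  if (sd(normalized_lengths) == 0 || sd(peak_counts) == 0)
    stop("undefined correlation: zero variance")
  r <- cor(normalized_lengths, peak_counts)
  list(r = r, r_squared = r^2)
}

#' Peak-length comparison across genomic feature classes
#'
#' One-way ANOVA of peak length by feature class followed by all
#' pairwise Tukey honestly-significant-difference comparisons, with
#' compact letter groupings (classes sharing a letter are not
#' significantly different at `alpha`).  Classes with fewer than two
#' peaks are excluded with a warning.
#'
#' @param annotated GRanges from [annotate_peaks()] (uses width and the
#'   `class` column; the `proximal` flag splits promoter into
#'   proximal/distal when `split_proximal` is TRUE).
#' @param alpha Familywise significance level for the letter display.
#' @param split_proximal Report proximal promoter peaks as their own
#'   group.
#' @return List with `anova` (data.frame: F, p, df), `tukey`
#'   (data.frame of pairwise comparisons) and `letters` (named
#'   character vector).
#' @export
region_length_comparison <- function(annotated, alpha = 0.05,
                                     split_proximal = FALSE) {
  grp <- as.character(annotated$class)
  if (split_proximal)
    grp[grp == "promoter" & annotated$proximal] <- "proximal_promoter"
  len <- width(annotated)
  tab <- table(grp)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding classes with < 2 peaks: ",
            paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    grp <- grp[keep]; len <- len[keep]
  }
  if (length(unique(grp)) < 2L)
    stop("at least two classes with >= 2 peaks are required")
  d <- data.frame(len = len, grp = factor(grp))
  fit <- aov(len ~ grp, data = d)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$grp
  pieces <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group1 = vapply(pieces, `[`, "", 1L),
                      group2 = vapply(pieces, `[`, "", 2L),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  letters <- letter_groups(levels(d$grp), tukey, alpha)
  list(anova = data.frame(F = an[1L, "F value"],
                          p = an[1L, "Pr(>F)"],
                          df_between = an[1L, "Df"],
                          df_within = an[2L, "Df"]),
       tukey = tukey, letters = letters)
}

# compact letter display by insert-and-absorb on the pairwise p matrix:
# start from one letter covering all groups, split on each significant
# pair, absorb redundant letters. Deterministic for a fixed group order.
letter_groups <- function(groups, tukey, alpha) {
  sig <- tukey[tukey$p_adj < alpha, c("group1", "group2"), drop = FALSE]
  sets <- list(groups)
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets)) {
      if (j != k && keep[j] && keep[k] &&
          all(new_sets[[j]] %in% new_sets[[k]]) &&
          (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k))
        keep[j] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  sets <- sets[order(vapply(sets, function(s)
    min(match(s, groups)), numeric(1)))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  out
}
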