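test_that("random regions are length-matched and length-weighted", {
  cs <- c(chr1 = 9000000L, chr2 = 1000000L)
  set.seed(3)
  rnd <- sample_random_regions(rep(100L, 10000L), cs)
  expect_true(all(width(rnd) == 100L))
  frac <- mean(as.character(seqnames(rnd)) == "chr1")
  # binomial 99% CI around 0.9 at n = 10000 is ~ +/- 0.008
  expect_gt(frac, 0.89)
  expect_lt(frac, 0.91)
  expect_true(all(end(rnd) <= cs[as.character(seqnames(rnd))]))
})

test_that("random-region sampling is seeded and handles edge lengths", {
  cs <- c(chrA = 500L, chrB = 100L)
  set.seed(12); a <- sample_random_regions(rep(50L, 20), cs)
  set.seed(12); b <- sample_random_regions(rep(50L, 20), cs)
  expect_identical(a, b)
  # a region as long as the longest chromosome is forced to start at 1
  set.seed(1)
  full <- sample_random_regions(500L, cs)
  expect_equal(start(full), 1L)
  expect_equal(as.character(seqnames(full)), "chrA")
  expect_error(sample_random_regions(501L, cs), "exceeds")
})

test_that("fold enrichment on a geneless genome is exactly 1 intergenic", {
  cs <- c(chrA = 50000L)
  empty <- tempfile(fileext = ".gtf"); writeLines(character(), empty)
  models <- read_gene_models(empty, cs)
  set.seed(4)
  pk <- random_peaks(50000L, 30)
  enr <- fold_enrichment(pk, models, cs, n_perm = 20)
  inter <- enr[enr$class == "intergenic", ]
  expect_equal(inter$fold, 1)
  expect_equal(inter$observed, 30L)
  expect_true(all(enr$observed[enr$class != "intergenic"] == 0L))
  # each permutation classifies every sampled region
  expect_equal(sum(enr$expected), length(pk), tolerance = 1e-6)
})

test_that("fold enrichment is reproducible under a fixed seed", {
  models <- simple_models()
  set.seed(8); pk <- random_peaks(900000L, 25)
  set.seed(99); e1 <- fold_enrichment(pk, models, models$chrom_sizes,
                                      n_perm = 5)
  set.seed(99); e2 <- fold_enrichment(pk, models, models$chrom_sizes,
                                      n_perm = 5)
  expect_identical(e1, e2)
})

test_that("uniform random peaks give fold ~ 1 in every populated class", {
  # genome with enough genes that all classes have mass
  set.seed(55)
  models <- random_toy_models(len = 60000L, n_genes = 8L)
  pk <- random_peaks(59000L, 400, min_w = 50L, max_w = 200L)
  enr <- fold_enrichment(pk, models, models$chrom_sizes, n_perm = 400)
  populated <- enr$expected > 5
  dev <- abs(enr$observed - enr$expected)
  # observed is one more draw from the same null: 4 SD slack
  expect_true(all(dev[populated] <= 4 * enr$sd[populated] + 1e-9))
})

test_that("normalized chromosome lengths follow the closed form", {
  nl <- normalized_chrom_lengths(c(A = 10L, B = 90L), 100)
  expect_equal(nl, c(A = 10, B = 90))
  expect_equal(sum(normalized_chrom_lengths(
    c(a = 123L, b = 456L, c = 789L), 777)), 777, tolerance = 1e-6)
  expect_equal(normalized_chrom_lengths(c(A = 5L, B = 5L), 0),
               c(A = 0, B = 0))
  expect_equal(normalized_chrom_lengths(c(only = 42L), 17),
               c(only = 17))
})

test_that("chromosome count correlation behaves at the extremes", {
  cs <- c(a = 100L, b = 200L, c = 300L, d = 400L)
  nl <- normalized_chrom_lengths(cs, 50)
  counts_prop <- setNames(c(5L, 10L, 15L, 20L), names(cs))
  cc <- chrom_correlation(nl, counts_prop)
  expect_equal(cc$r_squared, 1, tolerance = 1e-12)
  expect_error(chrom_correlation(nl[1:2], counts_prop[1:2]),
               "at least 3")
  expect_error(chrom_correlation(nl, setNames(rep(3L, 4), names(cs))),
               "zero variance")
})

test_that("count-length correlation is centered at zero under the null", {
  set.seed(77)
  cs <- setNames(sample(1000:5000, 12), paste0("c", 1:12))
  nl <- normalized_chrom_lengths(cs, 120)
  rs <- replicate(400, {
    counts <- setNames(sample(10:100, 12), names(cs))
    chrom_correlation(nl, counts)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("Tukey HSD comparison matches the studentized-range form", {
  # two far-separated classes among equals must get distinct letters
  set.seed(2)
  pk <- c(gr1(seq(1000, 49000, by = 1000),
              seq(1000, 49000, by = 1000) + 99),
          gr1(seq(101000, 149000, by = 1000),
              seq(101000, 149000, by = 1000) + 999))
  ann <- pk
  ann$class <- factor(rep(c("promoter", "intergenic"), each = 49),
                      levels = c("promoter", "tts", "exon", "intron",
                                 "intergenic"))
  ann$proximal <- FALSE
  res <- region_length_comparison(ann)
  expect_lt(res$tukey$p_adj[1L], 1e-6)
  expect_false(res$letters[["promoter"]] == res$letters[["intergenic"]])

  # independent studentized-range computation on a small fixed dataset
  lens <- c(10, 12, 11, 13, 30, 31, 29, 32, 50, 52, 49, 51)
  grp <- rep(c("exon", "intron", "promoter"), each = 4)
  g <- GRanges("chrA", IRanges(1, width = lens))
  g$class <- factor(grp, levels = c("promoter", "tts", "exon",
                                    "intron", "intergenic"))
  g$proximal <- FALSE
  res2 <- region_length_comparison(g)
  mse <- sum(tapply(lens, grp, function(x)
    sum((x - mean(x))^2))) / (12 - 3)
  means <- tapply(lens, grp, mean)
  q_obs <- abs(means[["intron"]] - means[["exon"]]) /
    sqrt(mse / 4)
  p_manual <- stats::ptukey(q_obs, nmeans = 3, df = 9,
                            lower.tail = FALSE)
  row <- res2$tukey[res2$tukey$group1 == "intron" &
                      res2$tukey$group2 == "exon", ]
  expect_equal(row$p_adj, p_manual, tolerance = 1e-8)
})

test_that("identical groups share one letter", {
  lens <- rep(c(100, 101, 99, 100), 3)
  g <- GRanges("chrA", IRanges(1, width = lens))
  g$class <- factor(rep(c("promoter", "exon", "intron"), each = 4),
                    levels = c("promoter", "tts", "exon", "intron",
                               "intergenic"))
  g$proximal <- FALSE
  res <- region_length_comparison(g)
  expect_true(all(res$letters == res$letters[[1L]]))
  expect_true(all(res$tukey$p_adj > 0.5))
})

test_that("classes with fewer than two peaks are excluded with warning", {
  g <- GRanges("chrA", IRanges(1, width = c(10, 12, 20, 22, 99)))
  g$class <- factor(c("exon", "exon", "intron", "intron", "tts"),
                    levels = c("promoter", "tts", "exon", "intron",
                               "intergenic"))
  g$proximal <- FALSE
  expect_warning(res <- region_length_comparison(g), "tts")
  expect_setequal(names(res$letters), c("exon", "intron"))
})
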