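samples_3x4 <- function() {
  data.frame(sample_id = sprintf("%s_r%d", rep(c("S1", "S2", "S3"),
                                               each = 4), 1:4),
             stage = rep(c("S1", "S2", "S3"), each = 4),
             replicate = rep(1:4, 3), stringsAsFactors = FALSE)
}

test_that("FPKM follows its closed form and scale invariances", {
  counts <- matrix(10L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(fpkm(counts, c(g1 = 1000), 1e6)[1, 1], 10)
  expect_equal(fpkm(matrix(0L, 1, 1, dimnames = list("g1", "s1")),
                    c(g1 = 1000), 1e6)[1, 1], 0)
  # doubling the library halves FPKM
  expect_equal(fpkm(counts, c(g1 = 1000), 2e6)[1, 1], 5)
  # joint count/library scaling leaves FPKM unchanged
  set.seed(1)
  m <- matrix(rpois(20, 50), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  lens <- setNames(c(500, 1000, 2000, 250), rownames(m))
  libs <- colSums(m)
  expect_equal(fpkm(m * 3L, lens, libs * 3), fpkm(m, lens, libs))
  expect_error(fpkm(m, lens[1:3], libs), "missing length")
})

test_that("expression filter requires > min_fpkm in >= min_samples of a stage", {
  sm <- samples_3x4()
  expr <- matrix(0, 3, 12, dimnames = list(paste0("g", 1:3),
                                           sm$sample_id))
  # g1: three samples above 1 in stage S1 -> kept
  expr["g1", sm$stage == "S1"] <- c(1.2, 1.2, 1.2, 0.1)
  # g2: exactly 1.0 everywhere -> dropped (strict >)
  expr["g2", ] <- 1.0
  # g3: two samples > 1 in each stage but never three -> dropped
  expr["g3", ] <- rep(c(2, 2, 0.5, 0.5), 3)
  expect_equal(filter_expressed(expr, sm), "g1")
})

test_that("median-of-ratios size factors have the closed form", {
  counts <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(size_factors(counts), c(a = 1, b = 1))
  # sample b exactly doubles sample a: factors proportional to (1, 2)
  counts2 <- counts; counts2[, "b"] <- counts[, "a"] * 2L
  sf <- size_factors(counts2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  # single sample
  expect_equal(size_factors(counts[, 1, drop = FALSE]), c(a = 1))
  # no feature nonzero everywhere: library-size fallback
  z <- matrix(c(5L, 0L, 0L, 10L), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(sfz <- size_factors(z), "library-size")
  expect_equal(unname(sfz["b"] / sfz["a"]), 2)
})

test_that("features identical across groups are called flat", {
  sm <- samples_3x4()[1:8, ]
  counts <- matrix(100L, 2, 8,
                   dimnames = list(c("f1", "f2"), sm$sample_id))
  res <- nb_differential(counts, sm, c("S2", "S1"))
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$p > 0.9))
  expect_true(all(res$direction == "ns"))
})

test_that("contrast reversal negates log2fc and preserves p", {
  sm <- samples_3x4()[1:8, ]
  set.seed(20)
  counts <- matrix(rnbinom(200 * 8, mu = 80, size = 10), 200, 8,
                   dimnames = list(paste0("f", 1:200), sm$sample_id))
  fwd <- nb_differential(counts, sm, c("S2", "S1"))
  rev_ <- nb_differential(counts, sm, c("S1", "S2"))
  expect_equal(rev_$log2fc, -fwd$log2fc)
  expect_equal(rev_$p, fwd$p)
})

test_that("all-zero features are excluded from testing and BH", {
  sm <- samples_3x4()[1:8, ]
  set.seed(21)
  counts <- rbind(matrix(rnbinom(50 * 8, mu = 50, size = 10), 50, 8),
                  matrix(0L, 5, 8))
  dimnames(counts) <- list(paste0("f", 1:55), sm$sample_id)
  res <- nb_differential(counts, sm, c("S2", "S1"))
  expect_true(all(is.na(res$p[51:55])))
  expect_true(all(is.na(res$padj[51:55])))
  tested <- res[1:50, ]
  expect_equal(tested$padj, p.adjust(tested$p, "BH"))
  expect_true(all(tested$padj >= tested$p - 1e-12))
  # BH monotone in p-rank
  o <- order(tested$p)
  expect_true(all(diff(tested$padj[o]) >= -1e-12))
})

test_that("NB test type-I error is near nominal (quick check)", {
  sm <- samples_3x4()[1:8, ]
  set.seed(30)
  rej <- replicate(5, {
    counts <- matrix(rnbinom(2000 * 8, mu = 100, size = 10), 2000, 8,
                     dimnames = list(paste0("f", 1:2000),
                                     sm$sample_id))
    res <- nb_differential(counts, sm, c("S2", "S1"))
    mean(res$p < 0.05)
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("log2fc estimates track an independent NB engine (DESeq2)", {
  skip_if_not_installed("DESeq2")
  sm <- samples_3x4()[1:8, ]
  set.seed(33)
  mu <- 2^runif(300, 4, 9)
  lfc_true <- sample(c(0, 0, 0, 1.5, -1.5), 300, replace = TRUE)
  counts <- cbind(
    matrix(rnbinom(300 * 4, mu = mu, size = 20), 300, 4),
    matrix(rnbinom(300 * 4, mu = mu * 2^lfc_true, size = 20), 300, 4))
  dimnames(counts) <- list(paste0("f", 1:300), sm$sample_id)
  ours <- nb_differential(counts, sm, c("S2", "S1"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, S4Vectors::DataFrame(condition = factor(sm$stage)),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "S2", "S1"))
  expect_gt(cor(ours$log2fc, ref$log2FoldChange), 0.95)
  expect_gt(cor(-log10(ours$p), -log10(ref$pvalue),
                use = "complete.obs", method = "spearman"), 0.8)
})

test_that("significance summaries count down/up/total", {
  rec <- data.frame(
    feature_id = paste0("f", 1:200),
    log2fc = c(rep(-2, 127), rep(2, 18), rep(0.2, 55)),
    padj = c(rep(0.001, 145), rep(0.5, 55)))
  expect_equal(significance_summary(rec),
               c(down = 127L, up = 18L, total = 145L))
  none <- data.frame(feature_id = "f1", log2fc = 0.1, padj = 0.9)
  expect_equal(significance_summary(none),
               c(down = 0L, up = 0L, total = 0L))
})

test_that("stage absent from the sheet or too few replicates error", {
  sm <- samples_3x4()[1:6, ]  # S2 has only 2 of its 4 rows here
  counts <- matrix(5L, 3, 6, dimnames = list(paste0("f", 1:3),
                                             sm$sample_id))
  expect_error(nb_differential(counts, sm, c("S9", "S1")), "S9")
  sm1 <- sm[sm$stage == "S1" | sm$replicate == 1, ]
  counts1 <- counts[, sm1$sample_id]
  expect_error(nb_differential(counts1, sm1, c("S2", "S1")),
               ">= 2 replicates")
})
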