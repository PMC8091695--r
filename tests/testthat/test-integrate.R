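test_that("promoter ACR map collects proximal peaks per gene", {
  models <- simple_models()
  # two peaks with midpoints in gPlus's proximal window (tss 5001),
  # one distal promoter peak, one intergenic
  pk <- gr1(c(4500, 4800, 3200, 200000),
            c(4700, 5000, 3400, 200100))
  pk$id <- paste0("p", 1:4)
  ann <- annotate_peaks(pk, models)
  m <- map_promoter_acrs(ann)
  expect_equal(m$map$gene_id, c("gPlus", "gPlus"))
  expect_setequal(m$map$acr_id, c("p1", "p2"))
  expect_equal(m$map$length, c(201L, 201L))
  expect_equal(m$count_distribution$n_acrs, 2L)
  # no proximal peaks: empty map
  ann2 <- annotate_peaks(gr1(300000, 300100), models)
  ann2$id <- "px"
  expect_equal(nrow(map_promoter_acrs(ann2)$map), 0L)
})

test_that("length statistics split single- and multi-ACR genes", {
  fake <- structure(list(map = data.frame(
    gene_id = c("g1", "g2", "g2", "g3", "g3", "g3"),
    acr_id = paste0("a", 1:6),
    length = c(100, 200, 300, 50, 60, 70))), class = "promoter_acr_map")
  expect_equal(acr_length_statistic(fake, "single"), c(g1 = 100))
  expect_equal(acr_length_statistic(fake, "max"),
               c(g2 = 300, g3 = 70))
  expect_equal(acr_length_statistic(fake, "total"),
               c(g2 = 500, g3 = 180))
})

test_that("90 distinct lengths split into three groups of 30", {
  lens <- setNames(sample(1001:1090), sprintf("g%02d", 1:90))
  grp <- assign_length_groups(lens)
  expect_equal(as.vector(table(grp$group)), c(30L, 30L, 30L))
  # top group holds the longest lengths
  expect_true(min(grp$length[grp$group == "top"]) >
                max(grp$length[grp$group == "middle"]))
})

test_that("a tie run straddling the bottom cut moves whole to the majority side", {
  # descending positions 60..62 share one length: 1 lands in middle,
  # 2 in bottom -> the run moves to bottom, giving 30/29/31
  lens <- c(200 - (1:59), rep(130, 3), 100 - (1:28))
  names(lens) <- sprintf("g%02d", seq_along(lens))
  grp <- assign_length_groups(lens)
  tab <- table(grp$group)
  expect_equal(as.vector(tab), c(30L, 29L, 31L))
  # the tied genes all share a group
  tied <- grp$group[grp$length == 130]
  expect_equal(as.character(unique(tied)), "bottom")
})

test_that("an all-equal degenerate run still yields a total partition", {
  lens <- setNames(rep(42, 30), sprintf("g%02d", 1:30))
  grp <- assign_length_groups(lens)
  expect_equal(nrow(grp), 30L)
  expect_equal(length(unique(grp$group)), 1L)
})

test_that("length grouping is order-invariant and rank-invariant", {
  set.seed(14)
  lens <- setNames(sample(c(50:70, rep(60, 6))), paste0("g", 1:27))
  g1 <- assign_length_groups(lens)
  g2 <- assign_length_groups(lens[sample(length(lens))])
  expect_equal(g1[order(g1$gene_id), c("gene_id", "group")],
               g2[order(g2$gene_id), c("gene_id", "group")])
  # monotone relabeling of lengths preserves membership
  g3 <- assign_length_groups(lens * 10 + 3)
  expect_equal(setNames(g3$group, g3$gene_id)[g1$gene_id],
               setNames(g1$group, g1$gene_id)[g1$gene_id])
  expect_error(assign_length_groups(lens[1:2]), "at least 3")
})

test_that("FPKM bins are left-closed right-open at 2/5/10/30", {
  v <- c(0, 1.99, 2.0, 4.99, 5, 9.99, 10, 29.99, 30, 31, 1000)
  expect_equal(as.character(bin_expression(v)),
               c("B1", "B1", "B2", "B2", "B3", "B3", "B4", "B4",
                 "B5", "B5", "B5"))
  expect_error(bin_expression(-1), "non-negative")
})

test_that("group-bin rows are percentages summing to 100", {
  groups <- setNames(factor(rep(c("top", "middle", "bottom"), each = 20),
                            levels = c("top", "middle", "bottom")),
                     paste0("g", 1:60))
  bins <- setNames(factor(rep("B5", 60), levels = paste0("B", 1:5)),
                   names(groups))
  tab <- group_bin_table(groups, bins)
  expect_equal(unname(tab[, "B5"]), c(100, 100, 100))
  expect_true(all(abs(rowSums(tab) - 100) < 1e-9))
  set.seed(6)
  bins2 <- setNames(factor(sample(paste0("B", 1:5), 60, TRUE),
                           levels = paste0("B", 1:5)), names(groups))
  tab2 <- group_bin_table(groups, bins2)
  expect_true(all(abs(rowSums(tab2) - 100) < 1e-9))
})

test_that("intensity-expression correlation finds exact linear pairs", {
  sm <- sprintf("s%d", 1:12)
  peak <- matrix(seq(2, 24, by = 2), 1, 12,
                 dimnames = list("pk1", sm))
  expr <- matrix(seq(4, 48, by = 4), 1, 12,
                 dimnames = list("g1", sm))
  map <- data.frame(gene_id = "g1", peak_id = "pk1")
  res <- intensity_expression_correlation(peak, expr, map)
  expect_equal(res$r, 1)
  # independent pairs center on zero
  set.seed(91)
  n <- 500
  pk <- matrix(rnorm(n * 12), n, 12, dimnames = list(paste0("p", 1:n), sm))
  ex <- matrix(rnorm(n * 12), n, 12, dimnames = list(paste0("g", 1:n), sm))
  m2 <- data.frame(gene_id = paste0("g", 1:n), peak_id = paste0("p", 1:n))
  r2 <- intensity_expression_correlation(pk, ex, m2)
  expect_lt(abs(mean(r2$r)), 0.05)
  # zero variance flagged
  pk0 <- matrix(5, 1, 12, dimnames = list("pz", sm))
  res0 <- intensity_expression_correlation(pk0, expr,
                                           data.frame(gene_id = "g1",
                                                      peak_id = "pz"))
  expect_true(res0$flagged)
})

test_that("DEG clustering recovers well-separated archetypes", {
  sm <- data.frame(sample_id = sprintf("%s_r%d",
                                       rep(c("S1", "S2", "S3"), each = 4),
                                       1:4),
                   stage = rep(c("S1", "S2", "S3"), each = 4))
  arch <- rbind(c(0, 0, 5), c(5, 0, 0), c(0, 5, 0),
                c(5, 5, 0), c(0, 5, 5), c(5, 0, 5))
  set.seed(17)
  truth <- rep(1:6, each = 25)
  expr <- t(vapply(truth, function(k)
    2^(arch[k, rep(1:3, each = 4)] + rnorm(12, 0, 0.2)),
    numeric(12)))
  dimnames(expr) <- list(paste0("g", seq_along(truth)), sm$sample_id)
  cl <- cluster_degs(expr, sm, k = 6)
  expect_gt(adjusted_rand_index(cl$clusters, truth), 0.9)
  # duplicated rows always co-cluster
  expect_equal(cl$clusters[["g1"]], cl$clusters[["g2"]])
  expect_error(cluster_degs(expr, sm, k = 1), "k must be")
  expect_error(cluster_degs(expr[1:3, ], sm, k = 6), "fewer genes")
})

test_that("cluster labels are deterministic given the seed", {
  sm <- data.frame(sample_id = paste0("s", 1:6),
                   stage = rep(c("S1", "S2", "S3"), each = 2))
  set.seed(3)
  expr <- matrix(2^rnorm(60 * 6), 60, 6,
                 dimnames = list(paste0("g", 1:60), sm$sample_id))
  set.seed(10); a <- cluster_degs(expr, sm, k = 4)
  set.seed(10); b <- cluster_degs(expr, sm, k = 4)
  expect_identical(a$clusters, b$clusters)
})

test_that("hypergeometric overlap p matches exact enumeration", {
  u <- paste0("g", 1:10)
  res <- overlap_significance(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  # exact enumeration oracle on small universes
  set.seed(41)
  for (i in 1:10) {
    N <- sample(6:20, 1)
    u <- paste0("x", 1:N)
    a <- sample(u, sample(2:(N - 1), 1))
    b <- sample(u, sample(2:(N - 1), 1))
    got <- overlap_significance(a, b, u)
    k_obs <- length(intersect(a, b))
    combs <- utils::combn(N, length(b))
    overlaps <- apply(combs, 2L, function(ix)
      length(intersect(u[ix], a)))
    expect_equal(got$p, mean(overlaps >= k_obs), tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(overlap_significance(u, u, u)$p, 1)
  big <- paste0("y", 1:1000)
  expect_gt(overlap_significance(big[1:3], big[501:503], big)$p, 0.9)
  expect_error(overlap_significance(c("zz"), u[1:2], u), "universe")
})

test_that("adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(13)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
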