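test_that("shannon matches closed forms, the oracle, and vegan", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon(c(100)), 0)
  expect_equal(shannon(c(1, 2, 3, 4)), 1.2798542258337, tolerance = 1e-10)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "negative")
  # invariant to zero padding; maximized by uniform
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(8, 15) + 1
    expect_equal(shannon(x), oracle_shannon(x), tolerance = 1e-12)
    expect_equal(shannon(c(x, 0, 0)), shannon(x))
    expect_lte(shannon(x), log(length(x)) + 1e-12)
  }
  tab <- random_table(10, 6, seed = 2)
  expect_equal(unname(alpha_diversity(tab)),
               unname(vegan::diversity(t(tab$counts))), tolerance = 1e-12)
})

test_that("rclr Aitchison distance is compositional and shared-support", {
  a <- c(4L, 8L, 2L, 10L)
  tab <- make_table(cbind(a, a, 10L * a))
  d <- rclr_aitchison_dist(tab)
  expect_equal(d[1, 2], 0)           # identical samples
  expect_equal(d[1, 3], 0)           # scale invariance
  expect_true(isSymmetric(d))
  # hand case: zero on shared support
  tab2 <- make_table(matrix(c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L), 4))
  expect_equal(rclr_aitchison_dist(tab2)[1, 2], 0)
  # rescaling: fully shared support reduces to plain rclr Euclidean
  m <- matrix(c(2L, 4L, 8L, 1L, 9L, 3L), 3)
  tab3 <- make_table(m)
  r <- apply(log(m), 2, function(v) v - mean(v))
  expect_equal(rclr_aitchison_dist(tab3)[1, 2],
               sqrt(sum((r[, 1] - r[, 2])^2)), tolerance = 1e-12)
  # undefined pair flagged NA
  tab4 <- make_table(matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L), 4))
  expect_warning(d4 <- rclr_aitchison_dist(tab4), "share < 2 taxa")
  expect_true(is.na(d4[1, 2]))
  # per-sample scalar multiplication leaves all distances unchanged
  tab5 <- random_table(8, 5, seed = 6)
  tab6 <- tab5
  tab6$counts[, 2] <- tab6$counts[, 2] * 7L
  expect_equal(rclr_aitchison_dist(tab5), rclr_aitchison_dist(tab6),
               tolerance = 1e-12)
})

test_that("pcoa recovers Euclidean configurations", {
  # points on a line at 0, 3, 7
  x <- c(0, 3, 7)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:3], letters[1:3])
  expect_warning(p <- pcoa(d, k = 2), "positive eigenvalues")
  ax1 <- p$coordinates[, 1]
  expect_equal(as.matrix(dist(ax1)), d, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(p$proportion[1], 1, tolerance = 1e-10)
  # full-rank Euclidean input is embedded exactly
  set.seed(4)
  pts <- matrix(rnorm(7 * 3), 7)
  D <- as.matrix(dist(pts))
  full <- pcoa(D, k = 3)
  expect_lt(max(abs(as.matrix(dist(full$coordinates)) - D)), 1e-8)
  # matches cmdscale up to axis sign
  cs <- cmdscale(D, k = 3)
  expect_equal(abs(unname(full$coordinates)), abs(unname(cs)),
               tolerance = 1e-8)
  # duplicate samples coincide
  D2 <- as.matrix(dist(rbind(pts, pts[1, ])))
  p2 <- pcoa(D2, k = 2)
  expect_lt(max(abs(p2$coordinates[8, ] - p2$coordinates[1, ])), 1e-8)
})

test_that("permanova matches adonis2 and detects separation", {
  tab <- random_table(12, 10, seed = 5)
  d <- as.matrix(vegan::vegdist(t(tab$counts)))
  g <- rep(c("a", "b"), each = 5)
  mine <- permanova(d, g, n_perm = 199, seed = 1)
  ado <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 199)
  expect_equal(mine$F, ado$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ado$R2[1], tolerance = 1e-10)
  # permutation equivariance: reordering samples with labels leaves F alone
  ord <- sample(10)
  expect_equal(permanova(d[ord, ord], g[ord], n_perm = 9, seed = 1)$F,
               mine$F, tolerance = 1e-12)
  # two widely separated clouds saturate significance
  set.seed(7)
  pts <- rbind(matrix(rnorm(10 * 2), 10), matrix(rnorm(10 * 2) + 50, 10))
  ds <- as.matrix(dist(pts))
  res <- permanova(ds, rep(c("x", "y"), each = 10), n_perm = 999, seed = 2)
  expect_equal(res$p_value, 0.001)
  expect_error(permanova(ds, c(rep("x", 19), "y")), "size 1")
  expect_true(res$p_value >= 1 / (res$n_permutations + 1))
})

test_that("simper decomposes Bray-Curtis exactly", {
  # toy 2x2: (0.8, 0.2) vs (0.2, 0.8) -> BC 0.6, each taxon 50%
  tab <- make_table(matrix(c(8L, 2L, 2L, 8L), 2))
  res <- simper(tab, c("g1", "g2"))
  expect_equal(attr(res, "mean_dissimilarity"), 0.6, tolerance = 1e-12)
  expect_equal(res$pct, c(50, 50), tolerance = 1e-10)
  expect_equal(res$cum_pct[2], 100, tolerance = 1e-10)
  # one taxon fully replaced by another: those two carry 100% between them
  tabx <- make_table(matrix(c(6L, 2L, 2L, 0L, 6L, 2L, 0L, 2L), 4))
  resx <- simper(tabx, c("g1", "g2"))
  expect_setequal(resx$taxon[1:2], c("t3", "t4"))
  expect_equal(resx$pct[1:2], c(50, 50), tolerance = 1e-10)
  expect_equal(resx$mean_contrib[3:4], c(0, 0), tolerance = 1e-12)
  expect_equal(attr(resx, "mean_dissimilarity"), 0.2, tolerance = 1e-12)
  # per-pair contributions sum to the pair Bray-Curtis (oracle)
  tab2 <- random_table(9, 6, seed = 8)
  p <- rel_abund(tab2)
  for (pair in list(c(1, 4), c(2, 5), c(3, 6))) {
    contrib <- oracle_simper_pair(p[, pair[1]], p[, pair[2]])
    expect_equal(sum(contrib), oracle_bray(p[, pair[1]], p[, pair[2]]),
                 tolerance = 1e-10)
  }
  # averaged contributions match vegan::simper on relative abundances
  g <- rep(c("A", "B"), each = 3)
  mine <- simper(tab2, g)
  sv <- summary(vegan::simper(t(p), g))[[1]]
  expect_equal(mine$mean_contrib[match(rownames(sv), mine$taxon)],
               sv$average, tolerance = 1e-10)
  expect_error(simper(tab2, rep("A", 6)), "2 groups")
  expect_true(all(mine$mean_contrib >= 0))
})

test_that("levins breadth hits its closed forms and bounds", {
  even <- make_table(matrix(rep(4L, 5), 1, 5))
  expect_equal(unname(levins_breadth(even)), 5)
  one <- make_table(matrix(c(9L, 0L, 0L, 1L, 1L, 1L), 2, 3, byrow = TRUE))
  expect_equal(unname(levins_breadth(one))[1], 1)
  half <- make_table(matrix(c(5L, 5L, 0L, 1L, 1L, 1L), 2, 3, byrow = TRUE))
  expect_equal(unname(levins_breadth(half))[1], 2)
  tab <- random_table(12, 7, seed = 9)
  B <- levins_breadth(tab, groups = rep(c("a", "b"), c(3, 4)))
  for (j in seq_len(12))
    expect_equal(unname(B[j]), oracle_levins(tab$counts[j, ]),
                 tolerance = 1e-12)
  expect_true(all(B >= 1 - 1e-12 & B <= 7 + 1e-12))
  expect_length(attr(B, "group_means"), 2L)
})

test_that("group_compare runs Wilcoxon, Kruskal-Wallis and Dunn", {
  # identical sets: rank-sum p is 1
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  res <- group_compare(v, g)
  expect_gt(res$p_value, 0.99)
  expect_equal(res$stars, "ns")
  # shifted by 3 SD: p < 0.001
  set.seed(11)
  v2 <- c(rnorm(15), rnorm(15) + 3)
  res2 <- group_compare(v2, rep(c("lo", "hi"), each = 15))
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$stars, "***")
  # 6 groups -> 15 Dunn pairs
  set.seed(12)
  v3 <- rnorm(36)
  g3 <- rep(paste0("s", 1:6), each = 6)
  res3 <- group_compare(v3, g3)
  expect_equal(nrow(res3$pairwise), 15L)
  expect_true(all(res3$pairwise$p_adj >= res3$pairwise$p_unadj - 1e-15))
  # kruskal statistic matches base R
  expect_equal(res3$H, unname(kruskal.test(v3, factor(g3))$statistic),
               tolerance = 1e-12)
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), "< 2 observations")
  expect_error(group_compare(v2, rep(c("a", "b"), each = 15),
                             design = "multi_group"), ">= 3")
})
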