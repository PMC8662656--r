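test_that("per-site statistics match their closed forms", {
  # group A: genotypes (0, 2) at one site -> p = 0.5, H_exp = 0.5,
  # H_obs = 0, pi = 0.5 * 4/3, F_IS = 1
  gm <- gm_from_groups(A = list(c(0L), c(2L)), B = list(c(0L), c(0L)))
  gs <- group_summary(gm)
  a <- gs[gs$group == "A", ]
  expect_equal(a$H_exp, 0.5)
  expect_equal(a$H_obs, 0)
  expect_equal(a$pi, 0.5 * 4 / 3, tolerance = 1e-12)
  expect_equal(a$F_IS, 1)
})

test_that("an all-heterozygous site gives F_IS = -1 exactly", {
  gm <- gm_from_groups(A = list(c(1L), c(1L)), B = list(c(0L), c(2L)))
  gs <- group_summary(gm)
  expect_equal(gs$F_IS[gs$group == "A"], -1)
})

test_that("private SNPs are counted by exclusive segregation", {
  # 12 loci; loci 1-7 segregate only in A, loci 8-10 segregate in several
  # groups, loci 11-12 are monomorphic everywhere
  row_of <- function(vals) { g <- integer(12); g[seq_along(vals)] <- vals; g }
  A <- list(row_of(rep(1L, 10)), row_of(rep(0L, 10)),
            row_of(rep(2L, 10)), row_of(rep(1L, 10)))
  B <- list(c(integer(7), 1L, 1L, 1L, 0L, 0L), integer(12),
            integer(12), integer(12))
  C <- list(c(integer(7), 2L, 2L, 0L, 0L, 0L), integer(12),
            integer(12), integer(12))
  D <- list(c(integer(7), 1L, 0L, 2L, 0L, 0L), integer(12),
            integer(12), integer(12))
  gm <- gm_from_groups(A = A, B = B, C = C, D = D)
  gs <- group_summary(gm)
  expect_identical(gs$private[gs$group == "A"], 7L)
  expect_true(all(gs$poly <= gs$variant))
  expect_true(all(gs$private <= gs$poly))
})

test_that("the printed two-population toy matches the frozen WC84 value", {
  # independently derived from the WC84 variance components: theta = -5/51
  gm <- gm_from_groups(A = list(0L, 0L, 1L, 2L), B = list(2L, 2L, 1L, 0L))
  r <- pairwise_fst(gm, "A", "B", n_perm = 0)
  expect_equal(r$estimate, -5 / 51, tolerance = 1e-12)
})

test_that("complete fixation gives F_ST = 1 and opposite Nei distance Inf", {
  gm <- gm_from_groups(A = list(rep(0L, 5), rep(0L, 5)),
                       B = list(rep(2L, 5), rep(2L, 5)))
  expect_equal(pairwise_fst(gm, "A", "B", n_perm = 0)$estimate, 1)
  nd <- nei_distance(gm, "A", "B")
  expect_identical(nd$n_infinite, 5L)
  expect_true(is.nan(nd$mean) || nd$mean == 0)   # no finite loci remain
})

test_that("random halves of a panmictic sample give near-zero F_ST", {
  ests <- vapply(1:100, function(i) {
    g <- simulate_panmictic(30, 1000, 98200, rng_seed = 7000 + i)
    grp <- rep(c("X", "Y"), each = 15)
    g2 <- genotype_matrix(g$gt, grp)
    pairwise_fst(g2, "X", "Y", n_perm = 0)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.01)
})

test_that("the permutation p-value is not anti-conservative under the null", {
  pv <- vapply(1:200, function(i) {
    g <- simulate_panmictic(16, 50, 20000, rng_seed = 8000 + i)
    g2 <- genotype_matrix(g$gt, rep(c("X", "Y"), each = 8))
    pairwise_fst(g2, "X", "Y", n_perm = 99, rng_seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(pv, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an undefined F_ST is reported as such, not as zero", {
  gm <- gm_from_groups(A = list(rep(0L, 3), rep(0L, 3)),
                       B = list(rep(0L, 3), rep(0L, 3)))
  r <- pairwise_fst(gm, "A", "B", n_perm = 10)
  expect_identical(r$status, "undefined")
  expect_true(is.na(r$estimate))
})

test_that("Nei distances match direct frequency-based evaluation", {
  gm <- gm_from_groups(A = list(rep(0L, 5), rep(0L, 5)),
                       B = list(c(0L, 1L, 1L, 0L, 2L), c(1L, 1L, 0L, 0L, 0L)))
  # locus-wise A is fixed ref; B frequencies p = (1,2,1,0,2)/4... computed
  # below directly from the definitions as an independent check
  pa <- rep(0, 5)
  pb <- colSums(rbind(c(0, 1, 1, 0, 2), c(1, 1, 0, 0, 0))) / 4
  jx <- pa^2 + (1 - pa)^2
  jy <- pb^2 + (1 - pb)^2
  jxy <- pa * pb + (1 - pa) * (1 - pb)
  d_exp <- -log(jxy / sqrt(jx * jy))
  nd <- nei_distance(gm, "A", "B")
  expect_equal(nd$per_locus, d_exp, tolerance = 1e-12)
  expect_equal(nd$mean, mean(d_exp), tolerance = 1e-12)
  # the closed-form case: A fixed, B at p = 0.5
  expect_equal(nd$per_locus[2], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  # identical frequencies -> zero distance
  gm0 <- gm_from_groups(A = list(c(0L, 1L), c(2L, 1L)),
                        B = list(c(1L, 1L), c(1L, 1L)))
  expect_equal(nei_distance(gm0, "A", "B")$per_locus, c(0, 0),
               tolerance = 1e-12)
})

test_that("PCA separates fixed groups and respects its invariances", {
  gt_a <- matrix(0L, 6, 40)
  gt_b <- matrix(2L, 6, 40)
  gm <- genotype_matrix(rbind(gt_a, gt_b), rep(c("A", "B"), each = 6))
  pc <- genotype_pca(gm, 3)
  expect_gt(min(abs(tapply(pc$coords[, 1], gm$group, mean))), 0.1)
  expect_true(all(sign(pc$coords[1:6, 1]) != sign(pc$coords[7:12, 1])))
  expect_gt(pc$varprop[1], 0.95)

  p <- scenario1_truth()
  g <- simulate_dataset(p, sample_config(6, 6, 6, 6), 300, rng_seed = 71)
  base <- genotype_pca(g, 2)
  # duplicated individual -> identical coordinates
  g_dup <- genotype_matrix(rbind(g$gt, g$gt[1, , drop = FALSE]),
                           c(g$group, g$group[1]))
  pcd <- genotype_pca(g_dup, 2)
  expect_equal(unname(pcd$coords[1, ]), unname(pcd$coords[25, ]),
               tolerance = 1e-8)
  # locus order invariance
  set.seed(73)
  perm <- sample(ncol(g$gt))
  g_perm <- genotype_matrix(g$gt[, perm], g$group)
  pcp <- genotype_pca(g_perm, 2)
  expect_equal(abs(pcp$coords), abs(base$coords), tolerance = 1e-8)
  # allele-label flips: coordinates equal up to sign
  flip <- seq(1, ncol(g$gt), by = 3)
  gt_f <- g$gt
  gt_f[, flip] <- 2L - gt_f[, flip]
  pcf <- genotype_pca(genotype_matrix(gt_f, g$group), 2)
  expect_equal(abs(pcf$coords), abs(base$coords), tolerance = 1e-8)
})

test_that("simulated divergence yields the expected PC cluster structure", {
  skip_if_not_installed("cluster")
  p <- scenario1_truth()
  g <- simulate_dataset(p, sample_config(8, 8, 8, 8), 800, rng_seed = 72)
  pc <- genotype_pca(g, 2)
  lab <- c(JR = 1, OH = 1, KK = 2, OT = 3)[g$group]   # {JR+OH}, {KK}, {OT}
  sil <- cluster::silhouette(lab, stats::dist(pc$coords[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
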