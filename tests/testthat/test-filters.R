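make_vs <- function(gt, chrom = NULL, pos = NULL, alt = NULL, dp = 50L,
                    gq = 99L) {
  L <- nrow(gt)
  n <- ncol(gt)
  variant_set(chrom %||% rep("sc1", L), pos %||% seq_len(L),
              rep("A", L), alt %||% rep("G", L), gt,
              dp = matrix(dp, L, n), gq = matrix(gq, L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("multi-allelic sites are removed regardless of other fields", {
  gt <- rbind(rep(c(0L, 1L), 10), rep(c(0L, 1L), 10))
  vs <- make_vs(gt, alt = c("G,T", "G"))
  out <- apply_filters(vs)
  expect_identical(out$report$n_out[1], 1L)
  expect_false(any(out$records$alt == "G,T"))
})

test_that("a site with exactly 50% heterozygotes is removed (strict bound)", {
  gt_half <- c(rep(1L, 10), rep(0L, 5), rep(2L, 5))     # Hobs = 0.5
  gt_ok <- c(rep(1L, 9), rep(0L, 6), rep(2L, 5))        # Hobs = 0.45
  out <- apply_filters(make_vs(rbind(gt_half, gt_ok)))
  expect_identical(out$report$n_out[out$report$criterion == "hobs"], 1L)
  expect_identical(length(out$records$pos), 1L)
})

test_that("a minor allele frequency exactly at the threshold is kept", {
  n <- 25                                  # maf 1/50 = 0.02 exactly
  gt_edge <- c(1L, rep(0L, n - 1))
  gt_low <- c(rep(0L, n))                  # monomorphic, maf 0
  out <- apply_filters(make_vs(rbind(gt_edge, gt_low)))
  expect_identical(out$report$n_out[out$report$criterion == "maf"], 1L)
})

test_that("the committed toy VCF reproduces its hand-enumerated report", {
  vcf <- system.file("extdata", "toy_filter.vcf", package = "bathypop")
  out <- apply_filters(read_vcf(vcf))
  expect_identical(out$report$n_in, c(12L, 11L, 11L, 11L, 11L, 11L, 11L))
  expect_identical(out$report$n_out, c(11L, 11L, 11L, 11L, 11L, 11L, 1L))
  # survivors of criteria 1-6 minus the 10 SNPs on the overloaded scaffold
  expect_identical(length(out$records$pos), 11L - 10L)
  expect_identical(unique(out$records$chrom), "scaffold_B")
})

test_that("genotype masking precedes the presence test (cascade order)", {
  # 5 of 20 genotypes at low depth: after masking, presence = 75% < 80%,
  # so the site must fall even though all genotypes were originally called
  gt <- matrix(rep(c(0L, 1L), 10), 2, 20, byrow = TRUE)
  dp <- matrix(50L, 2, 20)
  dp[1, 1:5] <- 2L
  vs <- variant_set(c("sc1", "sc2"), 1:2, c("A", "A"), c("G", "G"), gt,
                    dp = dp, gq = matrix(99L, 2, 20))
  out <- apply_filters(vs)
  expect_identical(out$report$genotypes_masked[2], 5L)
  expect_identical(out$report$n_out[out$report$criterion == "presence"], 1L)
})

test_that("the cascade is idempotent and its report is monotone", {
  g <- simulate_panmictic(30, 400, 20000, rng_seed = 31)
  vs <- add_gbs_noise(g, depth_mean = 8, missing_rate = 0.1, rng_seed = 32,
                      snps_per_scaffold = 12L)
  once <- apply_filters(vs)
  expect_true(all(once$report$n_out <= once$report$n_in))
  expect_identical(once$report$n_in[-1], once$report$n_out[-7])
  twice <- apply_filters(once$records)
  expect_identical(twice$records$gt, once$records$gt)
  expect_identical(twice$records$pos, once$records$pos)
  expect_true(all(twice$report$n_in == twice$report$n_out))
})

test_that("one SNP per scaffold is retained with deterministic selection", {
  gt <- matrix(0L, 14, 4)
  gt[, 1] <- 1L
  vs <- make_vs(gt, chrom = rep(c("a", "b", "c"), c(4, 1, 9)),
                pos = c(4:1, 1L, 9:1))
  first <- select_one_snp_per_locus(vs)
  expect_identical(length(first$pos), 3L)
  expect_true(all(first$pos == 1L))        # first by position
  r1 <- select_one_snp_per_locus(vs, method = "random", rng_seed = 5)
  r2 <- select_one_snp_per_locus(vs, method = "random", rng_seed = 5)
  expect_identical(r1$pos, r2$pos)
  expect_identical(length(r1$pos), 3L)
})

test_that("records without DP or GQ are refused by the cascade", {
  gt <- matrix(rep(c(0L, 1L), 10), 2, 20, byrow = TRUE)
  vs <- variant_set(c("sc1", "sc2"), 1:2, c("A", "A"), c("G", "G"), gt,
                    dp = matrix(50L, 2, 20), gq = NULL)
  expect_error(apply_filters(vs), "DP/GQ")
})
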